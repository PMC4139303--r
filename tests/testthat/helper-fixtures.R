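# Shared fixtures: small element panels and instrument plans used across the
# module tests. Everything is generated in code; no stored data.

panel10 <- c("B", "Mg", "Cr", "Mn", "Zn", "Rb", "Sr", "Sn", "Ba", "U")

fingerprints10 <- function(effect_size = 3, ...) {
  make_fingerprints(panel10, effect_size = effect_size, ...)
}

# deterministic instrument: no noise, no spikes
quiet_plan <- function(drift_slope = 0, seed = 1L, ...) {
  session_plan(noise_factor = 0, spike_fraction = 0,
               drift_slope = drift_slope, seed = seed, ...)
}

reference10 <- function() nist612_reference(c(panel10, "Ca"))

# small reduced surface dataset (noisy unless plan overridden)
small_surface <- function(n_mangrove = 12, n_reef = 20, plan = session_plan(seed = 42)) {
  fp <- fingerprints10()
  ds <- simulate_surface_dataset(fp, n_mangrove = n_mangrove, n_reef = n_reef,
                                 plan = plan)
  red <- reduce_runs(ds$runs, reference10())
  list(fingerprints = fp, runs = ds$runs, meta = ds$meta, reduced = red)
}

# draw a two-cluster composition table directly from fingerprints (no
# instrument simulation), for classifier tests
cluster_composition <- function(fp, n_per_class = 50, seed = 1L,
                                elements = names(fp$mangrove$element_means)) {
  set.seed(seed)
  local({
    draw <- function(fprint, habitat, n) {
      m <- fprint$element_means[elements]
      sdlog <- sqrt(log(1 + fprint$element_cv[elements]^2))
      X <- t(vapply(seq_len(n), function(i)
        stats::rlnorm(length(m), log(m), sdlog), numeric(length(m))))
      colnames(X) <- elements
      data.frame(run_id = sprintf("%s%03d", habitat, seq_len(n)),
                 habitat = habitat, X, stringsAsFactors = FALSE,
                 check.names = FALSE)
    }
    wide <- rbind(draw(fp$mangrove, "mangrove", n_per_class),
                  draw(fp$reef, "reef", n_per_class))
    tot <- rowSums(wide[elements])
    wide[elements] <- 100 * wide[elements] / tot
    attr(wide, "retained_elements") <- elements
    class(wide) <- c("composition_table", "data.frame")
    wide
  })
}
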