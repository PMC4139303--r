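#' Habitat elemental fingerprints
#'
#' Builds the pair of mangrove/reef elemental fingerprints that drive the
#' synthetic-data generator. Concentrations across fish within a habitat are
#' log-normal; the fingerprint stores the log-normal median (ppm) and a
#' relative dispersion per element. Mangrove otoliths carry elevated Ba, Cr,
#' Mn and Sn while reef otoliths carry elevated Rb and Sr; `effect_size` is
#' the fold-change applied to those discriminating elements (mangrove-elevated
#' elements are multiplied, reef-elevated elements divided). All other
#' elements share the same median in both habitats.
#'
#' @param elements character vector of element symbols (must appear in
#'   [element_catalog()]).
#' @param effect_size fold-change (> 1) separating the habitats on the
#'   discriminating elements.
#' @param cv relative dispersion of concentrations across fish within a
#'   habitat (log-normal coefficient of variation), recycled per element.
#' @param mangrove_elevated,reef_elevated element symbols carrying the habitat
#'   signal in each direction; symbols absent from `elements` are ignored.
#' @param seed optional integer; when given, baseline medians are jittered
#'   log-normally (sd 0.1 on the log scale) so repeated studies differ while
#'   remaining reproducible.
#' @return Named list with components `mangrove` and `reef`, each of class
#'   `habitat_fingerprint` with fields `habitat`, `element_means`,
#'   `element_cv`.
#' @export
#' @examples
#' fp <- make_fingerprints(c("Mn", "Sn", "Rb", "Sr", "Ba", "Cr", "B", "Mg"))
#' fp$mangrove$element_means["Mn"] / fp$reef$element_means["Mn"]
make_fingerprints <- function(elements,
                              effect_size = 3,
                              cv = 0.3,
                              mangrove_elevated = c("Ba", "Cr", "Mn", "Sn"),
                              reef_elevated = c("Rb", "Sr"),
                              seed = NULL) {
  if (!length(elements)) stop2("`elements` must be non-empty")
  assert_number(effect_size, "effect_size")
  if (effect_size <= 1) {
    stop2("`effect_size` must be > 1: a fold-change of 1 gives no habitat discrimination")
  }
  elements <- unique(elements)
  base <- element_catalog()
  unknown <- setdiff(elements, base$element)
  if (length(unknown)) {
    stop2("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  elements <- canonical_elements(setdiff(elements, "Ca"))
  reef_means <- setNames(base$reef_ppm[match(elements, base$element)], elements)
  if (!is.null(seed)) {
    reef_means <- with_seed(seed,
      reef_means * exp(rnorm(length(reef_means), 0, 0.1)))
  }
  mang_means <- reef_means
  up <- intersect(mangrove_elevated, elements)
  down <- intersect(reef_elevated, elements)
  mang_means[up] <- mang_means[up] * effect_size
  mang_means[down] <- mang_means[down] / effect_size
  cvs <- setNames(rep_len(cv, length(elements)), elements)
  fp <- function(habitat, means) {
    structure(list(habitat = habitat, element_means = means, element_cv = cvs),
              class = "habitat_fingerprint")
  }
  list(mangrove = fp("mangrove", mang_means), reef = fp("reef", reef_means))
}

#' Acquisition-session plan for the synthetic instrument
#'
#' Collects every knob of the simulated LA-ICP-MS acquisition: session layout
#' (8 otoliths per session bracketed by duplicate NIST 612 standards, a
#' standard after every ten ablations in transect mode), a linear sensitivity
#' drift per acquired run, the 1 Hz sampling of the 120 s analysis (30 s
#' blank + 90 s ablation), Poisson-like count noise, and outlier spikes.
#'
#' @param n_otoliths_per_session otoliths analyzed between the opening and
#'   closing standard pairs of a session.
#' @param standards_bracketing logical; duplicate standards at both ends of
#'   each session.
#' @param standard_every_n_ablations standard cadence in transect mode.
#' @param drift_slope relative sensitivity change per acquired run (unitless).
#' @param sampling_rate_hz detector readings per second.
#' @param noise_factor variance of a CPS reading is `noise_factor * mean`
#'   (Poisson-like); 0 switches noise off.
#' @param spike_fraction fraction of readings replaced by outlier spikes.
#' @param spike_factor spike magnitude as a multiple of the local window mean.
#' @param blank_cps expected blank (gas background) level, CPS.
#' @param sensitivity_cps_per_ppm instrument sensitivity, CPS per ppm, shared
#'   by all isotopes at run index 0.
#' @param site_sd between-site standard deviation of log-concentration within
#'   a habitat (0 = no site effect; the study design does not constrain it).
#' @param seed integer seed making every dataset built from the plan a pure
#'   function of its parameters.
#' @return Object of class `session_plan`.
#' @export
session_plan <- function(n_otoliths_per_session = 8,
                         standards_bracketing = TRUE,
                         standard_every_n_ablations = 10,
                         drift_slope = 0.002,
                         sampling_rate_hz = 1,
                         noise_factor = 1,
                         spike_fraction = 0.02,
                         spike_factor = 10,
                         blank_cps = 25,
                         sensitivity_cps_per_ppm = 2000,
                         site_sd = 0,
                         seed = 1L) {
  assert_number(n_otoliths_per_session, "n_otoliths_per_session", lower = 1)
  assert_number(standard_every_n_ablations, "standard_every_n_ablations", lower = 1)
  assert_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-6)
  assert_number(noise_factor, "noise_factor", lower = 0)
  assert_number(spike_fraction, "spike_fraction", lower = 0, upper = 1)
  assert_number(blank_cps, "blank_cps", lower = 0)
  assert_number(sensitivity_cps_per_ppm, "sensitivity_cps_per_ppm", lower = 1e-12)
  structure(list(
    n_otoliths_per_session = as.integer(n_otoliths_per_session),
    standards_bracketing = isTRUE(standards_bracketing),
    standard_every_n_ablations = as.integer(standard_every_n_ablations),
    drift_slope = drift_slope,
    sampling_rate_hz = sampling_rate_hz,
    noise_factor = noise_factor,
    spike_fraction = spike_fraction,
    spike_factor = spike_factor,
    blank_cps = blank_cps,
    sensitivity_cps_per_ppm = sensitivity_cps_per_ppm,
    site_sd = site_sd,
    seed = as.integer(seed)
  ), class = "session_plan")
}

#' Simulate one laser-ablation acquisition
#'
#' Produces the 120 s count-rate time series of a single ablation: 30 s of
#' gas blank followed by 90 s of ablation signal. The expected ablation CPS of
#' element *e* is `blank + S_e * ppm_e`, with sensitivity
#' `S_e = sensitivity_cps_per_ppm * (1 + drift_slope * run_index)`. Noise is
#' Gaussian with variance proportional to the expected CPS; a configurable
#' fraction of readings in both windows is replaced by spikes at
#' `spike_factor` times the local window mean. Standards are simulated from
#' the reference-material concentrations instead of `true_ppm`.
#'
#' @param true_ppm named vector of true element concentrations (ppm). Samples
#'   are given the internal-standard Ca concentration automatically when
#'   absent.
#' @param plan a [session_plan()].
#' @param run_index acquisition order within the session (drives drift).
#' @param role `"sample"` or `"standard"`.
#' @param run_id,session_id identifiers stamped on the run.
#' @param capture_habitat,capture_site,fish_id,spot_distance_um optional
#'   metadata carried through reduction.
#' @param reference named concentrations of the standard glass, used when
#'   `role = "standard"`.
#' @param ca_mass_fraction otolith Ca mass fraction for the sample matrix.
#' @param seed optional integer; when given, the run is drawn from its own
#'   seeded stream (otherwise the caller's RNG stream is used).
#' @return Object of class `ablation_run`: time vector, CPS matrix
#'   (time x element), window definitions, metadata, and a `truth` attribute
#'   recording programmed concentrations and sensitivities for verification.
#' @export
simulate_ablation_run <- function(true_ppm, plan = session_plan(),
                                  run_index = 0, role = c("sample", "standard"),
                                  run_id = "run1", session_id = "S1",
                                  capture_habitat = NA_character_,
                                  capture_site = NA_character_,
                                  fish_id = NA_character_,
                                  spot_distance_um = NA_real_,
                                  reference = nist612_reference(),
                                  ca_mass_fraction = otolith_ca_mass_fraction(),
                                  seed = NULL) {
  role <- match.arg(role)
  if (any(!is.finite(true_ppm)) || any(true_ppm < 0)) {
    stop2("`true_ppm` must be non-negative and finite")
  }
  assert_number(run_index, "run_index", lower = 0)
  with_seed(seed, {
    if (role == "standard") {
      elements <- canonical_elements(names(true_ppm))
      ppm <- reference[elements]
    } else {
      ppm <- true_ppm
      if (!("Ca" %in% names(ppm))) ppm <- c(ppm, Ca = ca_mass_fraction * 1e6)
      elements <- canonical_elements(names(ppm))
      ppm <- ppm[elements]
    }
    dt <- 1 / plan$sampling_rate_hz
    time_s <- seq(0, 120 - dt, by = dt)
    blank_win <- c(0, 30)
    abl_win <- c(30, 120)
    in_blank <- time_s >= blank_win[1] & time_s < blank_win[2]
    in_abl <- time_s >= abl_win[1] & time_s < abl_win[2]
    sens <- plan$sensitivity_cps_per_ppm * (1 + plan$drift_slope * run_index)
    cps <- matrix(0, nrow = length(time_s), ncol = length(elements),
                  dimnames = list(NULL, elements))
    for (e in elements) {
      expected <- ifelse(in_abl, plan$blank_cps + sens * ppm[[e]], plan$blank_cps)
      x <- expected
      if (plan$noise_factor > 0) {
        x <- rnorm(length(expected), expected, sqrt(plan$noise_factor * expected))
        x[x < 0] <- 0
      }
      if (plan$spike_fraction > 0) {
        for (win in list(in_blank, in_abl)) {
          idx <- which(win)
          n_spike <- rpois(1, plan$spike_fraction * length(idx))
          if (n_spike > 0) {
            hit <- sample(idx, min(n_spike, length(idx)))
            x[hit] <- plan$spike_factor * mean(expected[win])
          }
        }
      }
      cps[, e] <- x
    }
    structure(list(
      run_id = run_id, role = role, session_id = session_id,
      sequence_index = run_index,
      time_s = time_s, cps = cps,
      blank_window = blank_win, ablation_window = abl_win,
      capture_habitat = capture_habitat, capture_site = capture_site,
      fish_id = fish_id, spot_distance_um = spot_distance_um,
      truth = list(ppm = ppm, sensitivity = setNames(rep(sens, length(elements)), elements))
    ), class = "ablation_run")
  })
}

#' @export
print.ablation_run <- function(x, ...) {
  cat(sprintf("<ablation_run> %s (%s, session %s, index %d): %d elements x %d readings\n",
              x$run_id, x$role, x$session_id, x$sequence_index,
              ncol(x$cps), nrow(x$cps)))
  invisible(x)
}

draw_fish_ppm <- function(fingerprint, site_shift = NULL) {
  m <- fingerprint$element_means
  cv <- fingerprint$element_cv
  sdlog <- sqrt(log(1 + cv^2))
  if (!is.null(site_shift)) m <- m * exp(site_shift[names(m)])
  rlnorm(length(m), meanlog = log(m), sdlog = sdlog) |> setNames(names(m))
}

simulate_session_runs <- function(ppm_list, meta, plan, session_id, reference) {
  # layout: std, std, samples..., std, std  (sequence_index from 0)
  runs <- list()
  idx <- 0
  push_std <- function(runs, idx) {
    r <- simulate_ablation_run(setNames(rep(1, length(reference)), names(reference)),
                               plan, run_index = idx, role = "standard",
                               run_id = sprintf("%s_std%02d", session_id, idx),
                               session_id = session_id, reference = reference)
    c(runs, list(r))
  }
  if (plan$standards_bracketing) {
    runs <- push_std(runs, idx); idx <- idx + 1
    runs <- push_std(runs, idx); idx <- idx + 1
  }
  for (j in seq_along(ppm_list)) {
    m <- meta[j, ]
    runs <- c(runs, list(simulate_ablation_run(
      ppm_list[[j]], plan, run_index = idx, role = "sample",
      run_id = m$run_id, session_id = session_id,
      capture_habitat = m$habitat, capture_site = m$site,
      fish_id = m$fish_id, spot_distance_um = m$spot_distance_um,
      reference = reference)))
    idx <- idx + 1
  }
  if (plan$standards_bracketing) {
    runs <- push_std(runs, idx); idx <- idx + 1
    runs <- push_std(runs, idx)
  }
  runs
}

default_site_names <- function() {
  c("Gatope", "St Vincent", "Ouano", "Prony", "Noumea", "Nepoui",
    "Golonne", "Amos", "Tchambouenne", "Paama", "Port Bouquet")
}

#' Simulate the otolith-surface characterization dataset
#'
#' Emulates the habitat-characterization design: otolith surfaces of fish
#' caught in mangroves and on reefs, analyzed in sessions of
#' `plan$n_otoliths_per_session` otoliths bracketed by duplicate NIST 612
#' standards. Per-fish concentrations are log-normal draws from the habitat
#' fingerprint, with an optional site effect.
#'
#' @param fingerprints output of [make_fingerprints()].
#' @param n_mangrove,n_reef number of fish per habitat (defaults mirror the
#'   study design: 37 mangrove, 159 reef).
#' @param plan a [session_plan()]; its seed makes the dataset reproducible.
#' @param sites site labels cycled over fish within each habitat.
#' @param reference standard-glass concentrations.
#' @return List with `runs` (list of `ablation_run`, standards interleaved)
#'   and `meta` (per-fish data.frame).
#' @export
simulate_surface_dataset <- function(fingerprints,
                                     n_mangrove = 37, n_reef = 159,
                                     plan = session_plan(),
                                     sites = default_site_names(),
                                     reference = NULL) {
  elements <- names(fingerprints$mangrove$element_means)
  reference <- reference %||% nist612_reference(c(elements, "Ca"))
  with_seed(plan$seed, {
    habitat <- c(rep("mangrove", n_mangrove), rep("reef", n_reef))
    site <- c(rep_len(sites, n_mangrove), rep_len(sites, n_reef))
    n <- length(habitat)
    meta <- data.frame(
      run_id = sprintf("fish%03d", seq_len(n)),
      fish_id = sprintf("fish%03d", seq_len(n)),
      habitat = habitat, site = site,
      spot_distance_um = NA_real_,
      stringsAsFactors = FALSE
    )
    site_shift <- NULL
    if (plan$site_sd > 0) {
      usite <- unique(site)
      site_shift <- lapply(usite, function(s)
        setNames(rnorm(length(elements), 0, plan$site_sd), elements))
      names(site_shift) <- usite
    }
    ppm_list <- lapply(seq_len(n), function(i) {
      fp <- fingerprints[[habitat[i]]]
      draw_fish_ppm(fp, if (is.null(site_shift)) NULL else site_shift[[site[i]]])
    })
    chunks <- split(seq_len(n), ceiling(seq_len(n) / plan$n_otoliths_per_session))
    runs <- list()
    for (k in seq_along(chunks)) {
      ids <- chunks[[k]]
      runs <- c(runs, simulate_session_runs(
        ppm_list[ids], meta[ids, , drop = FALSE], plan,
        session_id = sprintf("S%02d", k), reference = reference))
    }
    list(runs = runs, meta = meta)
  })
}

#' Simulate one adult otolith transect
#'
#' Ten successive point-by-point ablations from the otolith core to 1260 um
#' in 140 um increments, bracketed by NIST 612 standards (one before, one
#' after the ten ablations, per the transect-mode cadence). The first
#' `residency_spots` spots are drawn from the mangrove fingerprint and the
#' remainder from the reef fingerprint, emulating an ontogenetic shift from a
#' mangrove nursery to the reef. Capture fork length is drawn from an
#' adult-size distribution and the capture otolith radius scaled
#' proportionally (with log-normal noise), so that Dahl-Lea back-calculation
#' at 1260 um lands near the cohort's juvenile length.
#'
#' @param residency_spots number of core-side spots (0..10) carrying the
#'   mangrove signature.
#' @param fingerprints output of [make_fingerprints()].
#' @param plan a [session_plan()].
#' @param fish_id,site identifiers.
#' @param length_mean_mm,length_sd_mm adult fork-length distribution (mm),
#'   truncated to \[180, 280\].
#' @param age_range_years annulus-count range sampled uniformly.
#' @param radius_noise_sd log-scale noise on the capture radius around its
#'   proportional expectation (11.25 um of radius per mm of fork length).
#' @param reference standard-glass concentrations.
#' @param seed optional integer seed for a self-contained draw.
#' @return List with `runs` (12 `ablation_run`s: standard, 10 spots,
#'   standard), `meta` (one-row data.frame: fish_id, site, age_years,
#'   L_cpt_mm, R_cpt_um) and `spots` (run_id, distance_um).
#' @export
simulate_adult_transect <- function(residency_spots, fingerprints,
                                    plan = session_plan(),
                                    fish_id = "F01", site = "Gatope",
                                    length_mean_mm = 224, length_sd_mm = 25,
                                    age_range_years = c(4, 18),
                                    radius_noise_sd = 0.05,
                                    reference = NULL, seed = NULL) {
  assert_number(residency_spots, "residency_spots", lower = 0, upper = 10)
  elements <- names(fingerprints$mangrove$element_means)
  reference <- reference %||% nist612_reference(c(elements, "Ca"))
  with_seed(seed, {
    distances <- seq(0, 1260, by = 140)
    habitat_truth <- c(rep("mangrove", residency_spots),
                       rep("reef", 10 - residency_spots))
    L_cpt <- min(max(rnorm(1, length_mean_mm, length_sd_mm), 180), 280)
    R_cpt <- 11.25 * L_cpt * exp(rnorm(1, 0, radius_noise_sd))
    R_cpt <- max(R_cpt, 1261)
    age <- sample(seq(age_range_years[1], age_range_years[2]), 1)
    ppm_list <- lapply(habitat_truth, function(h) draw_fish_ppm(fingerprints[[h]]))
    meta <- data.frame(
      run_id = sprintf("%s_spot%02d", fish_id, seq_along(distances)),
      fish_id = fish_id, habitat = NA_character_, site = site,
      spot_distance_um = distances, stringsAsFactors = FALSE
    )
    plan_t <- plan
    plan_t$n_otoliths_per_session <- plan$standard_every_n_ablations
    runs <- list(simulate_ablation_run(
      setNames(rep(1, length(reference)), names(reference)), plan_t,
      run_index = 0, role = "standard",
      run_id = sprintf("%s_std0", fish_id), session_id = fish_id,
      reference = reference))
    for (j in seq_along(distances)) {
      runs <- c(runs, list(simulate_ablation_run(
        ppm_list[[j]], plan_t, run_index = j, role = "sample",
        run_id = meta$run_id[j], session_id = fish_id,
        capture_habitat = NA_character_, capture_site = site,
        fish_id = fish_id, spot_distance_um = distances[j],
        reference = reference)))
    }
    runs <- c(runs, list(simulate_ablation_run(
      setNames(rep(1, length(reference)), names(reference)), plan_t,
      run_index = length(distances) + 1, role = "standard",
      run_id = sprintf("%s_std1", fish_id), session_id = fish_id,
      reference = reference)))
    list(runs = runs,
         meta = data.frame(fish_id = fish_id, site = site, age_years = age,
                           L_cpt_mm = L_cpt, R_cpt_um = R_cpt,
                           stringsAsFactors = FALSE),
         spots = data.frame(run_id = meta$run_id, distance_um = distances,
                            habitat_truth = habitat_truth,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a cohort of adult transects
#'
#' Default residency profile mirrors the study cohort: 20 adults of which 17
#' carry the mangrove signature at all ten spots and 3 only at the first two
#' (0 and 140 um), spread over four barrier-reef sites.
#'
#' @param fingerprints output of [make_fingerprints()].
#' @param residency_spots integer vector, one entry per fish.
#' @param plan a [session_plan()].
#' @param sites site labels cycled over fish.
#' @param ... forwarded to [simulate_adult_transect()].
#' @return List with `runs` (all ablation runs), `meta` (per-fish capture
#'   metadata) and `spots` (per-spot run ids, distances, truth labels).
#' @export
simulate_adult_cohort <- function(fingerprints,
                                  residency_spots = c(rep(10L, 17), rep(2L, 3)),
                                  plan = session_plan(),
                                  sites = c("Gatope", "Ouano", "Prony", "St Vincent"),
                                  ...) {
  with_seed(plan$seed + 1L, {
    runs <- list(); meta <- list(); spots <- list()
    site <- rep_len(sites, length(residency_spots))
    for (i in seq_along(residency_spots)) {
      tr <- simulate_adult_transect(residency_spots[i], fingerprints, plan,
                                    fish_id = sprintf("F%02d", i),
                                    site = site[i], ...)
      runs <- c(runs, tr$runs)
      meta[[i]] <- tr$meta
      spots[[i]] <- cbind(fish_id = tr$meta$fish_id, tr$spots,
                          stringsAsFactors = FALSE)
    }
    list(runs = runs, meta = do.call(rbind, meta), spots = do.call(rbind, spots))
  })
}

#' Synthetic strata of the archipelago survey
#'
#' Fourteen lagoon/reef/island strata with synthetic mangrove areas and coast
#' lengths: eight mainland-connected strata with mangroves and six remote
#' reefs and islands without. Areas and coast lengths are illustrative
#' synthetic values, not the cartographic measurements of any real survey.
#'
#' @return data.frame with columns `stratum`, `mangrove_area_km2`,
#'   `coast_length_km`.
#' @export
default_strata <- function() {
  data.frame(
    stratum = c("West Coast", "East Coast", "North Lagoon", "NE Lagoon",
                "SE Lagoon", "South Lagoon", "Ouvea", "Belep",
                "Chesterfield", "Entrecasteaux", "Astrolabe", "Petri",
                "Beautemps-Beaupre", "Lifou"),
    mangrove_area_km2 = c(140, 45, 18, 95, 12, 30, 3, 8, 0, 0, 0, 0, 0, 0),
    coast_length_km = c(420, 380, 260, 310, 240, 290, 120, 90,
                        150, 100, 60, 40, 50, 210),
    stringsAsFactors = FALSE
  )
}

#' Simulate a distance-sampling underwater visual census
#'
#' Generates per-fish UVC records over belt transects in each stratum. The
#' expected count of the target species per transect is a monotone increasing
#' function of the stratum's standardized mangrove area (area / coast
#' length); with `coupling = 1` a stratum without mangrove yields no target
#' fish at all. Perpendicular distances are uniform on \[0, 10\] m (i.e. the
#' raw, untruncated census half-width) and fork lengths normal.
#'
#' @param strata data.frame with `stratum`, `mangrove_area_km2`,
#'   `coast_length_km`.
#' @param coupling strength of the mangrove-abundance link in \[0, 1\]; 1 is
#'   a purely mangrove-driven abundance, 0 a uniform one.
#' @param transects_per_stratum transects surveyed per stratum.
#' @param peak_count expected target-species count per transect in the
#'   stratum with the largest standardized mangrove area.
#' @param species target species name.
#' @param fl_mean_cm,fl_sd_cm fork-length distribution (cm), truncated to
#'   \[12, 35\].
#' @param background_rate expected per-transect count of non-target records
#'   (two background species), exercising species filtering downstream.
#' @param seed integer seed.
#' @return data.frame of class `uvc_records`: `transect_id`, `stratum`,
#'   `species`, `count`, `fork_length_cm`, `perp_distance_m`.
#' @export
simulate_uvc_survey <- function(strata = default_strata(),
                                coupling = 1,
                                transects_per_stratum = 30,
                                peak_count = 6,
                                species = "Lutjanus fulviflamma",
                                fl_mean_cm = 25, fl_sd_cm = 4,
                                background_rate = 3,
                                seed = 1L) {
  if (is.null(strata) || !nrow(strata)) stop2("`strata` must be a non-empty data.frame")
  if (any(strata$mangrove_area_km2 < 0)) stop2("mangrove areas must be >= 0")
  if (any(strata$coast_length_km <= 0)) stop2("coast lengths must be > 0")
  assert_number(coupling, "coupling", lower = 0, upper = 1)
  with_seed(seed, {
    std <- strata$mangrove_area_km2 / strata$coast_length_km
    rel <- if (max(std) > 0) std / max(std) else std
    mu <- peak_count * (coupling * rel + (1 - coupling))
    out <- list()
    for (s in seq_len(nrow(strata))) {
      for (t in seq_len(transects_per_stratum)) {
        tid <- sprintf("%s_T%03d", gsub("\\s+", "", strata$stratum[s]), t)
        n_target <- rpois(1, mu[s])
        n_bg <- rpois(1, background_rate)
        n <- n_target + n_bg
        if (n == 0) next  # empty transects tracked via the "transects" attribute
        sp <- c(rep(species, n_target),
                sample(c("Chromis viridis", "Ctenochaetus striatus"),
                       n_bg, replace = TRUE))
        fl <- pmin(pmax(rnorm(n, fl_mean_cm, fl_sd_cm), 12), 35)
        out[[length(out) + 1L]] <- data.frame(
          transect_id = tid, stratum = strata$stratum[s], species = sp,
          count = 1L, fork_length_cm = fl,
          perp_distance_m = runif(n, 0, 10),
          stringsAsFactors = FALSE)
      }
    }
    rec <- if (length(out)) do.call(rbind, out) else data.frame(
      transect_id = character(), stratum = character(), species = character(),
      count = integer(), fork_length_cm = numeric(), perp_distance_m = numeric(),
      stringsAsFactors = FALSE)
    attr(rec, "transects") <- data.frame(
      transect_id = as.vector(t(outer(gsub("\\s+", "", strata$stratum),
                                      sprintf("T%03d", seq_len(transects_per_stratum)),
                                      paste, sep = "_"))),
      stratum = rep(strata$stratum, each = transects_per_stratum),
      stringsAsFactors = FALSE)
    class(rec) <- c("uvc_records", "data.frame")
    rec
  })
}
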