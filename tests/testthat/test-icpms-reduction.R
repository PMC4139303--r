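test_that("Tukey far-out fences remove spikes and keep clean series", {
  expect_equal(remove_outliers(c(10, 10, 10, 10, 10, 1000)), rep(10, 5))
  expect_equal(remove_outliers(rep(7, 10)), rep(7, 10))  # IQR 0: fences collapse
  expect_error(remove_outliers(c(1, 2, 3)), "at least 4")
  # oracle: brute-force fence recomputation on random data
  set.seed(31)
  for (i in 1:20) {
    x <- c(rnorm(40), sample(c(-50, 50), 3, replace = TRUE))
    q1 <- unname(quantile(x, 0.25, type = 7)); q3 <- unname(quantile(x, 0.75, type = 7))
    expected <- x[x >= q1 - 3 * (q3 - q1) & x <= q3 + 3 * (q3 - q1)]
    expect_identical(remove_outliers(x), expected)
  }
})

test_that("net signal is the background-subtracted ablation mean, floored", {
  run <- simulate_ablation_run(c(Mn = 1), quiet_plan(), 0, "sample")
  run$cps[, "Mn"] <- ifelse(run$time_s < 30, 100, 600)
  expect_equal(net_signal(run, "Mn"), 500)
  run$cps[, "Mn"] <- ifelse(run$time_s < 30, 600, 100)
  expect_equal(net_signal(run, "Mn"), 0)
})

test_that("drift-corrected sensitivity interpolates between standard brackets", {
  ref <- c(Mn = 38.7, Ca = 85050)
  mk_std <- function(idx, scale) {
    r <- simulate_ablation_run(c(Mn = 1), quiet_plan(), run_index = 0,
                               role = "standard", reference = ref,
                               run_id = paste0("std", idx))
    r$sequence_index <- idx
    r$cps <- r$cps * scale
    r
  }
  # S = 100 at index 0 and 200 at index 10 -> 150 at index 5
  base <- net_signal(mk_std(0, 1), "Mn") / ref[["Mn"]]
  stds <- list(mk_std(0, 100 / base), mk_std(10, 200 / base))
  expect_equal(drift_corrected_sensitivity(stds, ref, "Mn", 5), 150)
  # identical standards at both ends -> constant S everywhere
  stds2 <- list(mk_std(0, 1), mk_std(10, 1))
  s_vals <- vapply(c(1, 4, 9), function(i)
    drift_corrected_sensitivity(stds2, ref, "Mn", i), numeric(1))
  expect_equal(s_vals, rep(base, 3))
  expect_error(drift_corrected_sensitivity(stds2, ref, "Mn", 25), "bracketing")
})

test_that("noise-free sessions reduce to true ppm exactly, with drift on", {
  fp <- fingerprints10()
  plan <- quiet_plan(drift_slope = 0.005)
  ds <- simulate_surface_dataset(fp, n_mangrove = 2, n_reef = 3, plan = plan)
  red <- reduce_runs(ds$runs, reference10())
  for (r in ds$runs) {
    if (r$role != "sample") next
    got <- red[red$run_id == r$run_id, ]
    truth <- r$truth$ppm[got$element]
    expect_lt(max(abs(got$ppm - truth) / truth), 1e-9)
    expect_false(any(got$below_lod))
  }
})

test_that("concentration is scale-equivariant and linear in the analyte signal", {
  fp <- fingerprints10()
  ds <- simulate_surface_dataset(fp, 1, 1, plan = quiet_plan())
  role <- vapply(ds$runs, `[[`, character(1), "role")
  stds <- ds$runs[role == "standard"]
  smp <- ds$runs[role == "sample"][[1]]
  ref <- reference10()
  base <- concentration(smp, stds, ref)
  # multiply all CPS in sample and standards by a constant: unchanged
  smp2 <- smp; smp2$cps <- smp2$cps * 3.7
  stds2 <- lapply(stds, function(s) { s$cps <- s$cps * 3.7; s })
  expect_equal(concentration(smp2, stds2, ref), base, tolerance = 1e-12)
  # doubling one element's sample signal doubles its concentration only
  smp3 <- smp
  blank <- mean(smp3$cps[smp3$time_s < 30, "Mn"])
  abl_idx <- smp3$time_s >= 30
  smp3$cps[abl_idx, "Mn"] <- blank + 2 * (smp3$cps[abl_idx, "Mn"] - blank)
  got <- concentration(smp3, stds, ref)
  expect_equal(got[["Mn"]], 2 * base[["Mn"]], tolerance = 1e-9)
  expect_equal(got[setdiff(names(got), "Mn")],
               base[setdiff(names(base), "Mn")], tolerance = 1e-12)
})

test_that("LOD scales inversely with sensitivity and flags sub-LOD elements", {
  fp <- fingerprints10()
  ds <- simulate_surface_dataset(fp, 1, 1, plan = session_plan(seed = 3, spike_fraction = 0))
  role <- vapply(ds$runs, `[[`, character(1), "role")
  stds <- ds$runs[role == "standard"]
  smp <- ds$runs[role == "sample"][[1]]
  ref <- reference10()
  lod <- limit_of_detection(smp, stds, ref, "Mn")
  expect_gt(lod, 0)
  # doubling the element sensitivity (standard net CPS) halves the LOD
  stds2 <- lapply(stds, function(s) {
    abl <- s$time_s >= 30
    blank <- mean(s$cps[!abl, "Mn"])
    s$cps[abl, "Mn"] <- blank + 2 * (s$cps[abl, "Mn"] - blank)
    s
  })
  lod2 <- limit_of_detection(smp, stds2, ref, "Mn")
  expect_equal(lod2, lod / 2, tolerance = 1e-6)
  # zero blank variance -> LOD 0
  smp0 <- smp; smp0$cps[smp0$time_s < 30, "Mn"] <- 50
  expect_equal(limit_of_detection(smp0, stds, ref, "Mn"), 0)

  # an element programmed well below its LOD is flagged in >= 95% of runs
  plan <- session_plan(seed = 17, spike_fraction = 0)
  expected_lod <- 3 * sqrt(plan$blank_cps) / plan$sensitivity_cps_per_ppm
  low <- fp
  low$mangrove$element_means["U"] <- 0.3 * expected_lod
  low$mangrove$element_cv["U"] <- 1e-6
  ds2 <- simulate_surface_dataset(low, n_mangrove = 60, n_reef = 2, plan = plan)
  red2 <- reduce_runs(ds2$runs, ref)
  u <- red2[red2$element == "U" & red2$habitat == "mangrove", ]
  expect_gte(mean(u$below_lod), 0.95)
})

test_that("reduction is deterministic and honours the set-to-zero policy", {
  sur <- small_surface(n_mangrove = 3, n_reef = 3)
  role <- vapply(sur$runs, `[[`, character(1), "role")
  stds <- sur$runs[role == "standard"][1:4]
  smp <- sur$runs[role == "sample"][[1]]
  a <- reduce_run(smp, stds, reference10())
  b <- reduce_run(smp, stds, reference10())
  expect_identical(a, b)
  expect_true(all(a$element_ppm[a$below_lod] == 0))
  expect_true(all(a$element_ppm >= 0))
  # true-zero element comes back as below-LOD zero
  fp0 <- fingerprints10()
  ppm <- fp0$mangrove$element_means; ppm["Sn"] <- 1e-12
  run0 <- simulate_ablation_run(ppm, session_plan(seed = 5, spike_fraction = 0),
                                2, "sample")
  r0 <- reduce_run(run0, stds, reference10())
  expect_true(r0$below_lod[["Sn"]])
  expect_equal(r0$element_ppm[["Sn"]], 0)
})

test_that("standard CV matches its definition and the stated conventions", {
  ref <- c(Mn = 38.7, Ca = 85050)
  mk_std <- function(idx, scale) {
    r <- simulate_ablation_run(c(Mn = 1), quiet_plan(), 0, "standard",
                               reference = ref, run_id = paste0("s", idx))
    r$sequence_index <- idx
    abl <- r$time_s >= 30
    blank <- mean(r$cps[!abl, "Mn"])
    r$cps[abl, "Mn"] <- blank + scale * (r$cps[abl, "Mn"] - blank)
    r
  }
  # apparent concentrations in ratio 90:110 -> population CV exactly 10%
  stds <- list(mk_std(0, 90), mk_std(1, 110))
  expect_equal(standard_cv(stds, ref, "Mn", sd_convention = "population"), 10)
  expect_equal(standard_cv(list(mk_std(0, 1), mk_std(1, 1)), ref, "Mn"), 0)
  # oracle: brute-force recomputation on random standards
  set.seed(8)
  scales <- runif(4, 0.8, 1.2)
  stds4 <- lapply(seq_along(scales), function(i) mk_std(i - 1, scales[i]))
  net <- vapply(stds4, function(s) net_signal(s, "Mn"), numeric(1))
  apparent <- net / mean(net / ref[["Mn"]])
  expect_equal(standard_cv(stds4, ref, "Mn"),
               100 * sd(apparent) / mean(apparent), tolerance = 1e-12)
  expect_error(standard_cv(stds[1], ref, "Mn"), "at least 2")
})

test_that("session CSV round-trips ablation runs", {
  sur <- small_surface(n_mangrove = 2, n_reef = 2)
  f1 <- tempfile(fileext = ".csv")
  write_session_csv(sur$runs, f1)
  meta <- runs_metadata(sur$runs)
  back <- read_session_csv(f1, metadata = meta)
  expect_equal(length(back), length(sur$runs))
  orig <- sur$runs[order(vapply(sur$runs, `[[`, character(1), "session_id"),
                         vapply(sur$runs, `[[`, numeric(1), "sequence_index"))]
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$run_id, orig[[i]]$run_id)
    expect_equal(back[[i]]$cps, orig[[i]]$cps, tolerance = 1e-12)
    expect_equal(back[[i]]$capture_habitat, orig[[i]]$capture_habitat)
  }
  # reduction of the round-tripped runs matches the original reduction
  expect_equal(as.data.frame(reduce_runs(back, reference10())),
               as.data.frame(sur$reduced), tolerance = 1e-10)
  unlink(f1)
})
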