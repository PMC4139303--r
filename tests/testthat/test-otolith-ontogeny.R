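test_that("Dahl-Lea back-calculation is the exact proportional model", {
  expect_equal(dahl_lea(2520, 2520, 250), 250)       # identity at capture
  expect_equal(dahl_lea(1260, 2520, 224), 112)       # juvenile cutoff length
  expect_equal(dahl_lea(630, 2520, 224), 56)         # halving R halves L
  expect_equal(dahl_lea(0, 2520, 224), 0)            # core maps to zero
  expect_equal(dahl_lea(seq(0, 1260, 140), 2520, 224),
               seq(0, 1260, 140) / 2520 * 224)
  expect_error(dahl_lea(3000, 2520, 224), "exceeds")
  expect_error(dahl_lea(-1, 2520, 224), ">= 0")
  expect_error(dahl_lea(100, 0, 224), "R_cpt")
})

make_spot_comp <- function(fp, truth, seed) {
  set.seed(seed)
  els <- names(fp$mangrove$element_means)
  rows <- lapply(truth, function(h) {
    m <- fp[[h]]$element_means
    sdlog <- sqrt(log(1 + fp[[h]]$element_cv^2))
    stats::rlnorm(length(m), log(m), sdlog)
  })
  X <- do.call(rbind, rows)
  colnames(X) <- els
  X <- 100 * X / rowSums(X)
  data.frame(distance_um = seq(0, 1260, 140), X,
             stringsAsFactors = FALSE, check.names = FALSE)
}

test_that("transect classification labels spots and back-calculates lengths", {
  fp <- fingerprints10(effect_size = 8)
  comp <- cluster_composition(fp, n_per_class = 60, seed = 2)
  clf <- train_forest(comp, spec = forest_spec(n_trees = 300, seed = 4))

  spots_m <- make_spot_comp(fp, rep("mangrove", 10), seed = 5)
  pr <- adult_profile("F1", "Gatope", 6, 224, 2520, spots_m)
  pr <- classify_transect(pr, clf)
  expect_true(all(pr$spots$predicted_habitat == "mangrove"))
  expect_equal(pr$spots$length_mm, spots_m$distance_um / 2520 * 224)
  expect_false(is.unsorted(pr$spots$length_mm))  # monotone along transect

  spots_r <- make_spot_comp(fp, rep("reef", 10), seed = 6)
  pr_r <- classify_transect(adult_profile("F2", "Ouano", 8, 240, 2700, spots_r), clf)
  expect_true(all(pr_r$spots$predicted_habitat == "reef"))

  # spot independence: perturbing other spots leaves a spot's label unchanged
  spots_mix <- spots_m
  spots_mix[3:10, names(fp$mangrove$element_means)] <-
    spots_r[3:10, names(fp$mangrove$element_means)]
  pr_mix <- classify_transect(adult_profile("F3", "Prony", 7, 230, 2600, spots_mix), clf)
  expect_equal(pr_mix$spots$predicted_habitat[1:2],
               pr$spots$predicted_habitat[1:2])

  bad <- spots_m[, setdiff(names(spots_m), "Mn")]
  expect_error(classify_transect(adult_profile("F4", "x", 5, 200, 2400, bad), clf),
               "Mn")
})

test_that("profile invariants are enforced", {
  fp <- fingerprints10()
  spots <- make_spot_comp(fp, rep("reef", 10), seed = 1)
  expect_error(adult_profile("F1", "s", 5, 224, 1200, spots), "R_cpt_um")
  short <- spots[1:9, ]
  expect_error(adult_profile("F1", "s", 5, 224, 2520, short), "10 spots|140 um")
  shuffled <- spots[c(2, 1, 3:10), ]
  expect_error(adult_profile("F1", "s", 5, 224, 2520, shuffled), "increasing")
})

test_that("occupancy profile aggregates proportions and lengths", {
  fp <- fingerprints10(effect_size = 8)
  comp <- cluster_composition(fp, n_per_class = 60, seed = 3)
  clf <- train_forest(comp, spec = forest_spec(n_trees = 300, seed = 9))
  # 17 full mangrove residents + 3 early-only residents
  truths <- c(lapply(1:17, function(i) rep("mangrove", 10)),
              lapply(1:3, function(i) c("mangrove", "mangrove", rep("reef", 8))))
  profiles <- lapply(seq_along(truths), function(i) {
    spots <- make_spot_comp(fp, truths[[i]], seed = 100 + i)
    classify_transect(adult_profile(sprintf("F%02d", i), "s", 6, 224, 2520, spots), clf)
  })
  occ <- occupancy_profile(profiles)
  expect_equal(attr(occ, "cohort_size"), 20)
  expect_equal(occ$prop_mangrove[occ$distance_um <= 140], c(1, 1))
  expect_equal(occ$prop_mangrove[occ$distance_um >= 280], rep(0.85, 8))
  expect_equal(occ$mean_length_mm, seq(0, 1260, 140) / 2520 * 224)
  # juvenile-use rules
  calls_early <- vapply(profiles, juvenile_habitat_call, logical(1), rule = "early")
  calls_through <- vapply(profiles, juvenile_habitat_call, logical(1), rule = "throughout")
  expect_equal(sum(calls_early), 20)
  expect_equal(sum(calls_through), 17)
  # all-reef profile is false under both rules
  reef_pr <- classify_transect(
    adult_profile("R1", "s", 5, 200, 2400, make_spot_comp(fp, rep("reef", 10), 999)), clf)
  expect_false(juvenile_habitat_call(reef_pr, "early"))
  expect_false(juvenile_habitat_call(reef_pr, "throughout"))
  # mixed grids are rejected
  p2 <- profiles
  p2[[1]]$spots$distance_um <- p2[[1]]$spots$distance_um + 1
  expect_error(occupancy_profile(p2), "grids")
})
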