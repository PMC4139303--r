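rec <- function(tid, stratum, species, count, fl, d) {
  data.frame(transect_id = tid, stratum = stratum, species = species,
             count = count, fork_length_cm = fl, perp_distance_m = d,
             stringsAsFactors = FALSE)
}

test_that("truncation keeps the 5 m belt with a closed boundary", {
  r <- rec(c("t1", "t1", "t2"), "s", "sp", 1, 20, c(6.2, 5.0, 3.1))
  out <- truncate_uvc(r)
  expect_equal(out$perp_distance_m, c(5.0, 3.1))
  expect_equal(nrow(truncate_uvc(r[0, ])), 0)
})

test_that("transect density and biomass follow the belt geometry", {
  r <- rec("t1", "s", "sp", c(3, 7), 20, c(1, 2))
  expect_equal(transect_density(r), 10 / 500)        # 0.02 fish m^-2
  expect_equal(transect_density(r[0, ]), 0)
  expect_equal(transect_density(r) * 500, sum(r$count))
  lw <- data.frame(species = "sp", a = 0.01, b = 3)
  one <- rec("t1", "s", "sp", 1, 20, 1)
  expect_equal(transect_biomass(one, lw), 0.01 * 20^3 / 500)  # 0.16 g m^-2
  expect_equal(transect_biomass(one[0, ], lw), 0)
  lw0 <- data.frame(species = "sp", a = 2, b = 0)
  expect_equal(transect_biomass(rec("t", "s", "sp", 1, 35, 1), lw0),
               transect_biomass(rec("t", "s", "sp", 1, 12, 1), lw0))
  expect_error(transect_biomass(one, data.frame(species = "other", a = 1, b = 2)),
               "sp")
  # invariance to splitting a count-c record into c singletons
  grouped <- rec("t1", "s", "sp", 5, 20, 1)
  split_up <- rec("t1", "s", "sp", rep(1, 5), 20, 1)
  expect_equal(transect_density(grouped), transect_density(split_up))
  expect_equal(transect_biomass(grouped, lw), transect_biomass(split_up, lw))
})

test_that("stratum summaries match a brute-force recomputation", {
  strata <- data.frame(stratum = c("A", "B"),
                       mangrove_area_km2 = c(10, 0),
                       coast_length_km = c(100, 50))
  lw <- default_lw_coefficients()
  sp <- "Lutjanus fulviflamma"
  r <- rbind(
    rec("A_T1", "A", sp, 1, 25, 2), rec("A_T1", "A", sp, 1, 22, 7),
    rec("A_T2", "A", sp, 2, 30, 4),
    rec("A_T3", "A", "Chromis viridis", 3, 8, 1),
    rec("B_T1", "B", "Chromis viridis", 1, 7, 2))
  transects <- data.frame(
    transect_id = c("A_T1", "A_T2", "A_T3", "A_T4", "B_T1", "B_T2"),
    stratum = c("A", "A", "A", "A", "B", "B"), stringsAsFactors = FALSE)
  s <- stratum_summary(r, strata, transects = transects)
  a <- s[s$stratum == "A", ]
  # truncation removes the 7 m record; occurrence 2 of 4 transects
  expect_equal(a$occurrence_pct, 50)
  expect_equal(a$density_fish_m2, mean(c(1 / 500, 2 / 500, 0, 0)))
  lwa <- lw$a[lw$species == sp]; lwb <- lw$b[lw$species == sp]
  expect_equal(a$biomass_g_m2,
               mean(c(lwa * 25^lwb / 500, 2 * lwa * 30^lwb / 500, 0, 0)))
  expect_equal(a$std_mangrove_km2_km, 0.1)
  b <- s[s$stratum == "B", ]
  expect_equal(b$density_fish_m2, 0)
  expect_false(b$species_present)
  expect_false(b$mangrove_present)
  expect_warning(
    stratum_summary(r, rbind(strata, data.frame(stratum = "C",
      mangrove_area_km2 = 1, coast_length_km = 1)), transects = transects),
    "no transects")
})

test_that("presence chi-square matches the closed form on 2x2 tables", {
  mk <- function(mang, spp) data.frame(mangrove_present = mang,
                                       species_present = spp)
  # perfect association over 14 strata: chi-square equals n
  perfect <- mk(rep(c(TRUE, FALSE), c(8, 6)), rep(c(TRUE, FALSE), c(8, 6)))
  res <- presence_chi_square(perfect)
  expect_equal(res$chi_square, 14)
  expect_equal(res$df, 1L)
  expect_lt(res$p_value, 2e-4)
  # independence -> 0
  indep <- mk(rep(c(TRUE, FALSE), 10), rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  expect_equal(presence_chi_square(indep)$chi_square, 0)
  # 2x2 perfect with 4 strata -> 4 (n (ad-bc)^2 / product of margins)
  expect_equal(presence_chi_square(mk(c(T, T, F, F), c(T, T, F, F)))$chi_square, 4)
  # agreement with the standard implementation, no continuity correction
  set.seed(2)
  mang <- c(TRUE, TRUE, FALSE, sample(c(TRUE, FALSE), 9, replace = TRUE))
  spp <- c(TRUE, FALSE, FALSE, sample(c(TRUE, FALSE), 9, replace = TRUE))
  got <- presence_chi_square(mk(mang, spp))
  ref <- suppressWarnings(stats::chisq.test(table(mang, spp), correct = FALSE))
  expect_equal(got$chi_square, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(presence_chi_square(mk(rep(TRUE, 6), rep(c(T, F), 3))),
               "zero margin")
})

test_that("Spearman correlation uses midranks and the t approximation", {
  x <- c(0.1, 0.5, 0.9, 1.4, 2.2)
  expect_equal(spearman_correlation(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  # ties: agree with cor() on midranks and cor.test's asymptotic p
  set.seed(5)
  xt <- c(1, 1, 2, 3, 3, 4, 5, 5)
  yt <- c(2, 1, 1, 4, 4, 3, 5, 5)
  got <- spearman_correlation(xt, yt)
  expect_equal(got$rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  ref <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman",
                                          exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:3, 3:1), "at least 4")
})

test_that("maximal coupling yields a perfect presence table and rho near 1", {
  recs <- simulate_uvc_survey(coupling = 1, transects_per_stratum = 40, seed = 9)
  s <- stratum_summary(recs, default_strata())
  res <- presence_chi_square(s)
  expect_equal(res$chi_square, nrow(s))  # perfect 2x2 association
  tests <- mangrove_association_tests(s)
  rho_d <- tests$value[tests$statistic == "spearman_density"]
  expect_gt(rho_d, 0.9)
})
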