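test_that("univariate pseudo-F equals the classical one-way ANOVA F", {
  set.seed(11)
  for (i in 1:5) {
    y <- rnorm(24) + rep(c(0, 0.8, 1.5), each = 8)
    g <- rep(letters[1:3], each = 8)
    pm <- permanova_oneway(matrix(y, ncol = 1), g, n_perm = 49, seed = i)
    f_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(pm$pseudo_F, f_aov, tolerance = 1e-10)
    expect_equal(pm$df_between, 2L)
    expect_equal(pm$df_within, 21)
  }
})

test_that("distance-based sums of squares match the raw-coordinate identity", {
  # Anderson identity: for Euclidean distances the partition equals the
  # classical multivariate one computed from group centroids
  set.seed(21)
  X <- matrix(rnorm(30 * 4), 30, 4)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  pm <- permanova_oneway(X, g, n_perm = 9, seed = 1)
  grand <- colMeans(X)
  ss_total <- sum(sweep(X, 2, grand)^2)
  ss_within <- sum(unlist(lapply(levels(g), function(lev) {
    Xi <- X[g == lev, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  })))
  f_manual <- ((ss_total - ss_within) / 2) / (ss_within / 27)
  expect_equal(pm$pseudo_F, f_manual, tolerance = 1e-10)
  expect_equal(unname(pm$ss["total"]), ss_total, tolerance = 1e-10)
  expect_equal(unname(pm$ss["within"]), ss_within, tolerance = 1e-10)
})

test_that("PERMANOVA agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(33)
  X <- matrix(rnorm(40 * 3), 40, 3)
  X[1:20, 1] <- X[1:20, 1] + 1
  g <- rep(c("m", "r"), each = 20)
  pm <- permanova_oneway(X, g, n_perm = 999, seed = 2)
  ad <- vegan::adonis2(dist(X) ~ g, permutations = 999)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-10)
  # permutation p-values from the same null should agree closely
  expect_lt(abs(pm$p_value - ad$`Pr(>F)`[1]), 0.05)
})

test_that("separated groups reach the minimum attainable p-value", {
  # groups large enough that a random relabeling essentially never redraws
  # the original split, so every permuted F falls below the observed one
  set.seed(50)
  X <- rbind(matrix(0, 12, 2), matrix(100, 12, 2)) + rnorm(48, 0, 1e-3)
  g <- rep(c("a", "b"), each = 12)
  pm <- permanova_oneway(X, g, n_perm = 999, seed = 7)
  expect_equal(pm$p_value, 1 / 1000)
  expect_error(permanova_oneway(X, rep(c("a", "b"), c(1, 23)), 99, 1), "singleton")
  expect_error(permanova_oneway(matrix(1, 24, 1), g, 99, 1), "constant|identical")
})

test_that("type-I error of the permutation test is near nominal", {
  # null: labels carry no information; alpha = 0.05 on the 199-permutation grid
  set.seed(99)
  n_sim <- 400
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    y <- matrix(rnorm(16), ncol = 1)
    g <- rep(c("a", "b"), each = 8)
    p <- permanova_oneway(y, g, n_perm = 199, seed = i)$p_value
    if (p <= 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("per-element tests flag the planted contrast and reject degenerate input", {
  # only Mn is shifted so the closure of the percent transform leaves the
  # shared-mean elements essentially null (Mn is trace-level next to Sr)
  fp <- make_fingerprints(panel10, effect_size = 3,
                          mangrove_elevated = "Mn",
                          reef_elevated = character(0))
  comp <- cluster_composition(fp, n_per_class = 40, seed = 12)
  res <- univariate_permanovas(comp, n_perm = 199, seed = 5,
                               elements = c("Mn", "Mg"))
  expect_lt(res$Mn$p_value, 0.01)   # planted mangrove-elevated element
  expect_gt(res$Mg$p_value, 0.05)   # shared-mean element
  tab <- permanova_table(res)
  expect_equal(tab$scope, c("Mn", "Mg"))
  expect_equal(tab$F[1], res$Mn$pseudo_F)
  comp$flat <- 50
  expect_error(univariate_permanovas(comp, elements = "flat", n_perm = 9),
               "constant|identical")
})

test_that("arcsin-sqrt PCA matches an eigen-decomposition oracle", {
  fp <- fingerprints10()
  comp <- cluster_composition(fp, n_per_class = 15, seed = 3)
  pca <- arcsin_sqrt_pca(comp)
  els <- composition_elements(comp)
  Z <- asin(sqrt(as.matrix(comp[els]) / 100))
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Zc), symmetric = TRUE)
  expect_equal(pca$sdev^2, ev$values[seq_along(pca$sdev)], tolerance = 1e-8)
  for (k in 1:2) {
    expect_equal(abs(sum(pca$loadings[, k] * ev$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(sum(pca$var_explained), 1)
  # endpoints of the transform
  expect_equal(asin(sqrt(0 / 100)), 0)
  expect_equal(asin(sqrt(100 / 100)), pi / 2)
  comp$Mn[1] <- 101
  expect_error(arcsin_sqrt_pca(comp), "\\[0, 100\\]")
})
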