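#' One-way PERMANOVA from its permutation definition
#'
#' Pseudo-F for a one-way design computed from pairwise Euclidean distances:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` summed analogously within
#' each group, `SS_between = SS_total - SS_within`, and
#' `F = (SS_between / (a-1)) / (SS_within / (N-a))` for `a` groups and `N`
#' observations. Significance by unrestricted random permutation of the group
#' labels, with the observed statistic included in the reference set:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param X observation-by-variable numeric matrix (or data.frame of numeric
#'   columns); a single column gives the univariate test, whose pseudo-F
#'   equals the classical one-way ANOVA F.
#' @param groups group labels, at least 2 groups of at least 2 observations.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return Object of class `permanova`: `pseudo_F`, `df_between`,
#'   `df_within`, `p_value`, `n_permutations`, `seed`, `ss` components.
#' @export
permanova_oneway <- function(X, groups, n_perm = 999, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  groups <- factor(groups)
  n <- nrow(X)
  if (length(groups) != n) stop2("`groups` must match the rows of `X`")
  a <- nlevels(groups)
  if (a < 2) stop2("need at least 2 groups")
  if (any(table(groups) < 2)) stop2("every group needs at least 2 observations (singleton group)")
  if (any(apply(X, 2, function(col) all(col == col[1])))) {
    if (ncol(X) == 1) stop2("constant column: zero variance, pseudo-F undefined")
  }
  d2 <- as.matrix(dist(X))^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  if (ss_total == 0) stop2("all observations identical: zero total variance")
  ssw <- function(g) {
    G <- model_matrix_groups(g)
    sum(colSums((d2 %*% G) * G) / (2 * colSums(G)))
  }
  f_stat <- function(g) {
    ss_within <- ssw(g)
    ss_between <- ss_total - ss_within
    (ss_between / (a - 1)) / (ss_within / (n - a))
  }
  ss_within_obs <- ssw(groups)
  f_obs <- f_stat(groups)
  with_seed(seed, {
    f_perm <- vapply(seq_len(n_perm), function(i) f_stat(sample(groups)), numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  structure(list(
    pseudo_F = f_obs, df_between = a - 1L, df_within = n - a,
    p_value = p, n_permutations = as.integer(n_perm), seed = seed,
    ss = c(total = ss_total, within = ss_within_obs,
           between = ss_total - ss_within_obs)
  ), class = "permanova")
}

model_matrix_groups <- function(g) {
  G <- matrix(0, length(g), nlevels(g))
  G[cbind(seq_along(g), as.integer(g))] <- 1
  G
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("One-way PERMANOVA (Euclidean): F_%d,%d = %.4g, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}

#' Per-element one-way PERMANOVAs
#'
#' Runs [permanova_oneway()] on each element column of a composition table
#' (univariate tests comparing the element between habitats).
#'
#' @param composition a `composition_table` (or any data.frame whose element
#'   columns are named by element symbol).
#' @param groups group labels (default: the table's `habitat` column).
#' @param elements element columns to test (default: all retained).
#' @param n_perm,seed forwarded to [permanova_oneway()]; each element gets a
#'   deterministic child seed so tests are independent and reproducible.
#' @return Named list of `permanova` objects, one per element.
#' @export
univariate_permanovas <- function(composition, groups = composition$habitat,
                                  elements = NULL, n_perm = 999, seed = 1L) {
  elements <- elements %||% composition_elements(composition)
  out <- lapply(seq_along(elements), function(i) {
    permanova_oneway(composition[, elements[i], drop = FALSE], groups,
                     n_perm = n_perm, seed = child_seed(seed, i))
  })
  names(out) <- elements
  out
}

#' Tidy PERMANOVA results
#' @param results list of `permanova` objects (e.g. from
#'   [univariate_permanovas()]); names become the `scope` column.
#' @return data.frame with columns scope, F, df_between, df_within, p,
#'   n_perm, seed.
#' @export
permanova_table <- function(results) {
  if (inherits(results, "permanova")) results <- list(overall = results)
  data.frame(
    scope = names(results) %||% sprintf("test%d", seq_along(results)),
    F = vapply(results, `[[`, numeric(1), "pseudo_F"),
    df_between = vapply(results, `[[`, integer(1), "df_between"),
    df_within = vapply(results, `[[`, numeric(1), "df_within"),
    p = vapply(results, `[[`, numeric(1), "p_value"),
    n_perm = vapply(results, `[[`, integer(1), "n_permutations"),
    seed = vapply(results, function(r) as.numeric(r$seed), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Arcsine-square-root PCA of a composition table
#'
#' Applies the variance-stabilizing transform `x -> arcsin(sqrt(x/100))` to
#' the percent composition, centers columns, and extracts principal axes by
#' singular value decomposition.
#'
#' @param composition a `composition_table` (percent values in \[0, 100\]).
#' @param elements element columns (default: all retained).
#' @return List of class `arcsin_pca`: `scores`, `loadings`, `sdev`,
#'   `var_explained` (fractions summing to 1).
#' @export
arcsin_sqrt_pca <- function(composition, elements = NULL) {
  elements <- elements %||% composition_elements(composition)
  X <- as.matrix(composition[, elements, drop = FALSE])
  if (any(X < 0 | X > 100)) {
    stop2("composition values must be percentages in [0, 100]")
  }
  Z <- asin(sqrt(X / 100))
  pc <- prcomp(Z, center = TRUE, scale. = FALSE)
  structure(list(
    scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
    var_explained = pc$sdev^2 / sum(pc$sdev^2)
  ), class = "arcsin_pca")
}

#' @export
print.arcsin_pca <- function(x, ...) {
  cat("arcsin-sqrt PCA:", ncol(x$scores), "axes;",
      sprintf("PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$var_explained[1],
              if (length(x$var_explained) > 1) 100 * x$var_explained[2] else 0))
  invisible(x)
}
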