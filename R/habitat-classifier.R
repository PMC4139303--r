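#' Random-forest specification
#'
#' The forest protocol: each tree is grown on a random 75% of the samples
#' drawn without replacement, and every sample is evaluated out-of-bag (OOB)
#' by majority vote over the trees that did not see it. 5000 trees by
#' default so each sample is predicted many times; tests and searches can
#' lower `n_trees`.
#'
#' @param n_trees trees per forest (default 5000).
#' @param sample_fraction per-tree subsample fraction, without replacement
#'   (default 0.75).
#' @param seed integer seed.
#' @param tie_break `"prevalent"` (exact vote ties go to the most prevalent
#'   training class, i.e. reef in the study design) or a class label.
#' @return Object of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 5000, sample_fraction = 0.75, seed = 1L,
                        tie_break = "prevalent") {
  assert_number(n_trees, "n_trees", lower = 1)
  assert_number(sample_fraction, "sample_fraction", lower = 1e-9, upper = 1 - 1e-9)
  structure(list(n_trees = as.integer(n_trees),
                 sample_fraction = sample_fraction,
                 seed = as.integer(seed),
                 tie_break = tie_break),
            class = "forest_spec")
}

#' Train the habitat random forest
#'
#' Fits a classification forest on the chosen element columns of a percent
#' composition table and populates the out-of-bag confusion matrix.
#'
#' @param composition a `composition_table` (or data.frame with the element
#'   columns).
#' @param labels habitat label per row (default: the `habitat` column).
#' @param elements element subset to use (default: all retained).
#' @param spec a [forest_spec()].
#' @return Object of class `habitat_classifier`: the fitted forest, element
#'   subset, spec, class levels, most prevalent class, and `oob_confusion`
#'   (a `confusion_matrix`).
#' @export
train_forest <- function(composition, labels = composition$habitat,
                         elements = NULL, spec = forest_spec()) {
  elements <- elements %||% composition_elements(composition)
  if (!length(elements)) stop2("`elements` must be non-empty")
  missing_el <- setdiff(elements, names(composition))
  if (length(missing_el)) {
    stop2("element column(s) missing from composition: ",
          paste(missing_el, collapse = ", "))
  }
  y <- factor(labels)
  if (nlevels(y) < 2) stop2("labels contain a single class; cannot train a classifier")
  X <- as.data.frame(composition[, elements, drop = FALSE])
  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = spec$n_trees,
    sample.fraction = spec$sample_fraction,
    replace = FALSE,
    seed = spec$seed,
    num.threads = 1,
    oob.error = TRUE
  )
  oob <- fit$predictions
  keep <- !is.na(oob)
  cm <- table(true = y[keep], predicted = factor(oob[keep], levels = levels(y)))
  prevalent <- names(which.max(table(y)))
  structure(list(
    elements = elements, spec = spec, forest = fit,
    classes = levels(y), prevalent_class = prevalent,
    oob_confusion = confusion_percentages(cm)
  ), class = "habitat_classifier")
}

#' @export
print.habitat_classifier <- function(x, ...) {
  cat(sprintf("<habitat_classifier> elements: %s | %d trees | OOB overall %.1f%%\n",
              paste(x$elements, collapse = ", "), x$spec$n_trees,
              x$oob_confusion$overall_pct))
  invisible(x)
}

#' Classification-matrix percentages
#'
#' Per-class and overall percent correct from a true-by-predicted count
#' table, reported to one decimal. A class with an empty row is reported as
#' `NA` and contributes nothing to the overall denominator.
#'
#' @param counts square matrix or table of counts, rows = true class,
#'   columns = predicted class (matching order).
#' @return Object of class `confusion_matrix`: `counts`, `per_class_pct`,
#'   `overall_pct`.
#' @export
#' @examples
#' confusion_percentages(matrix(c(31, 2, 6, 157), 2,
#'   dimnames = list(c("mangrove", "reef"), c("mangrove", "reef"))))
confusion_percentages <- function(counts) {
  counts <- as.matrix(counts)
  if (!length(counts) || nrow(counts) != ncol(counts)) {
    stop2("`counts` must be a non-empty square true-by-predicted table")
  }
  rt <- rowSums(counts)
  diag_counts <- diag(counts)
  per_class <- ifelse(rt > 0, round(100 * diag_counts / rt, 1), NA_real_)
  overall <- round(100 * sum(diag_counts) / sum(counts), 1)
  structure(list(counts = counts,
                 per_class_pct = setNames(per_class, rownames(counts)),
                 overall_pct = overall),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  pc <- paste(sprintf("%s %.1f%%", names(x$per_class_pct), x$per_class_pct),
              collapse = ", ")
  cat(sprintf("correct: %s; overall %.1f%%\n", pc, x$overall_pct))
  invisible(x)
}

subset_strings <- function(candidates) {
  k <- length(candidates)
  subs <- list()
  for (size in seq_len(k)) {
    cmb <- combn(candidates, size, simplify = FALSE)
    subs <- c(subs, cmb)
  }
  subs
}

oob_overall_accuracy <- function(composition, y, elements, spec) {
  X <- as.data.frame(composition[, elements, drop = FALSE])
  fit <- ranger::ranger(x = X, y = y, num.trees = spec$n_trees,
                        sample.fraction = spec$sample_fraction,
                        replace = FALSE, seed = spec$seed,
                        num.threads = 1, oob.error = TRUE)
  oob <- fit$predictions
  keep <- !is.na(oob)
  100 * mean(oob[keep] == y[keep])
}

#' Exhaustive element-subset search
#'
#' Evaluates a random forest for every non-empty subset of the candidate
#' elements (`2^k - 1` forests) and ranks subsets by overall out-of-bag
#' accuracy. Each subset is evaluated with a seed derived deterministically
#' from the spec seed and the subset's position in the canonical enumeration,
#' so the ranking is reproducible and subset evaluations independent. Ties
#' are broken in favour of fewer elements, then canonical lexicographic
#' order. The best subset is refitted into the returned classifier.
#'
#' @param composition a `composition_table`.
#' @param labels habitat label per row (default: `habitat` column).
#' @param candidates candidate elements, at most 20 (the search is
#'   exponential in their number).
#' @param spec a [forest_spec()]; lower `n_trees` (e.g. 500) keeps the
#'   search affordable.
#' @return Object of class `element_search`: `ranking` (data.frame subset /
#'   n_elements / oob_accuracy, best first) and `best` (a
#'   `habitat_classifier` fitted on the winning subset).
#' @export
exhaustive_search <- function(composition, labels = composition$habitat,
                              candidates = NULL, spec = forest_spec(n_trees = 500)) {
  candidates <- canonical_elements(candidates %||% composition_elements(composition))
  k <- length(candidates)
  if (k < 1) stop2("need at least one candidate element")
  if (k > 20) {
    stop2(sprintf("%d candidates means %.3g subsets; cap the candidate list at 20",
                  k, 2^k - 1))
  }
  y <- factor(labels)
  subs <- subset_strings(candidates)
  acc <- numeric(length(subs))
  for (i in seq_along(subs)) {
    spec_i <- spec
    spec_i$seed <- child_seed(spec$seed, i)
    acc[i] <- oob_overall_accuracy(composition, y, subs[[i]], spec_i)
  }
  subset_lab <- vapply(subs, paste, character(1), collapse = "+")
  nel <- lengths(subs)
  ord <- order(-acc, nel, subset_lab)
  ranking <- data.frame(subset = subset_lab[ord], n_elements = nel[ord],
                        oob_accuracy = acc[ord],
                        stringsAsFactors = FALSE, row.names = NULL)
  best_elements <- subs[[ord[1]]]
  best <- train_forest(composition, labels, best_elements, spec)
  structure(list(ranking = ranking, best = best,
                 candidates = candidates, seed = spec$seed),
            class = "element_search")
}

#' @export
print.element_search <- function(x, ...) {
  cat(sprintf("<element_search> %d subsets of {%s}\n", nrow(x$ranking),
              paste(x$candidates, collapse = ", ")))
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Predict habitat labels
#'
#' Majority vote over all trees, with exact 50/50 ties resolved by the
#' spec's deterministic tie-break (most prevalent training class by
#' default).
#'
#' @param object a `habitat_classifier`.
#' @param newdata data.frame containing the classifier's element columns.
#' @param ... unused.
#' @return Factor of habitat labels, one per row of `newdata`.
#' @export
predict.habitat_classifier <- function(object, newdata, ...) {
  missing_el <- setdiff(object$elements, names(newdata))
  if (length(missing_el)) {
    stop2("missing element column(s): ", paste(missing_el, collapse = ", "))
  }
  X <- as.data.frame(newdata[, object$elements, drop = FALSE])
  pr <- stats::predict(object$forest, data = X, predict.all = TRUE,
                       num.threads = 1)$predictions
  classes <- object$classes
  tie_to <- if (identical(object$spec$tie_break, "prevalent")) {
    object$prevalent_class
  } else object$spec$tie_break
  votes <- t(apply(pr, 1, tabulate, nbins = length(classes)))
  lab <- character(nrow(votes))
  for (i in seq_len(nrow(votes))) {
    top <- which(votes[i, ] == max(votes[i, ]))
    lab[i] <- if (length(top) > 1 && tie_to %in% classes[top]) {
      tie_to
    } else if (length(top) > 1) {
      classes[min(top)]
    } else classes[top]
  }
  factor(lab, levels = classes)
}
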