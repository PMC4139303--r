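#' Per-group detection rate of an element
#'
#' Fraction of samples, within each habitat (or site) group, whose
#' concentration of the element is above its limit of detection.
#'
#' @param samples `reduced_samples` long data.frame (see [reduce_runs()]).
#' @param element element symbol.
#' @param group_by `"habitat"` or `"site"`.
#' @return Named vector of detection fractions per group.
#' @export
detection_rate <- function(samples, element, group_by = c("habitat", "site")) {
  if (length(group_by) == 1 && !group_by %in% c("habitat", "site")) {
    stop2(sprintf("unknown grouping key `%s` (use \"habitat\" or \"site\")", group_by))
  }
  group_by <- match.arg(group_by)
  sub <- samples[samples$element == element & !is.na(samples[[group_by]]), ]
  if (!nrow(sub)) stop2(sprintf("no samples with non-missing `%s` for %s", group_by, element))
  tapply(!sub$below_lod, sub[[group_by]], mean)
}

#' Element-retention rule
#'
#' An element is kept for statistical analysis iff (1) it is detected (above
#' LOD) in at least `detect_threshold` of the otoliths in at least one
#' habitat or one site, and (2) its coefficient of variation in the NIST 612
#' external standard is below `cv_threshold` percent.
#'
#' @param samples `reduced_samples` long data.frame.
#' @param cv_by_element named vector of standard CVs in percent (see
#'   [standards_cv_table()]); must cover every candidate element.
#' @param detect_threshold detection-rate threshold (default 0.70).
#' @param cv_threshold standard-CV threshold in percent (default 10).
#' @param candidates element symbols to screen (default: every element in
#'   `samples` except Ca).
#' @return Character vector of retained elements, in canonical order.
#' @export
retain_elements <- function(samples, cv_by_element,
                            detect_threshold = 0.70, cv_threshold = 10,
                            candidates = NULL) {
  candidates <- candidates %||% setdiff(unique(samples$element), "Ca")
  candidates <- canonical_elements(candidates)
  missing_cv <- setdiff(candidates, names(cv_by_element))
  if (length(missing_cv)) {
    stop2("no standard CV available for: ", paste(missing_cv, collapse = ", "))
  }
  keep <- vapply(candidates, function(e) {
    rates <- c(
      tryCatch(detection_rate(samples, e, "habitat"), error = function(err) NA_real_),
      tryCatch(detection_rate(samples, e, "site"), error = function(err) NA_real_)
    )
    rates <- rates[!is.na(rates)]
    length(rates) > 0 &&
      max(rates) >= detect_threshold &&
      cv_by_element[[e]] < cv_threshold
  }, logical(1))
  candidates[keep]
}

#' Detection/CV retention report
#'
#' Screening diagnostics behind [retain_elements()]: per-element maximum
#' habitat and site detection rates, standard CV and the retention decision.
#'
#' @inheritParams retain_elements
#' @return data.frame with one row per candidate element.
#' @export
retention_report <- function(samples, cv_by_element,
                             detect_threshold = 0.70, cv_threshold = 10,
                             candidates = NULL) {
  candidates <- candidates %||% setdiff(unique(samples$element), "Ca")
  candidates <- canonical_elements(candidates)
  retained <- retain_elements(samples, cv_by_element, detect_threshold,
                              cv_threshold, candidates)
  max_rate <- function(e, by) {
    r <- tryCatch(detection_rate(samples, e, by), error = function(err) NA_real_)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  }
  data.frame(
    element = candidates,
    max_habitat_detection = vapply(candidates, max_rate, numeric(1), by = "habitat"),
    max_site_detection = vapply(candidates, max_rate, numeric(1), by = "site"),
    standard_cv_pct = unname(cv_by_element[candidates]),
    retained = candidates %in% retained,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Percent-of-total compositional transform
#'
#' Converts each sample's retained-element concentrations to percent of their
#' sum, the harmonization used to pool analyses from two different ICP-MS
#' instruments. Rows whose retained elements are all zero (everything below
#' LOD) cannot be normalized; they are dropped with a warning. Calcium, the
#' internal standard, is never part of the denominator.
#'
#' @param samples `reduced_samples` long data.frame.
#' @param retained character vector of retained elements (non-empty).
#' @return Wide data.frame of class `composition_table`: `run_id`,
#'   `habitat`, `site`, `fish_id`, `spot_distance_um`, then one percent
#'   column per retained element (rows sum to 100). The retained set is kept
#'   in the `"retained_elements"` attribute.
#' @export
percent_transform <- function(samples, retained) {
  if (!length(retained)) stop2("`retained` must be non-empty")
  retained <- canonical_elements(setdiff(retained, "Ca"))
  sub <- samples[samples$element %in% retained, ]
  ids <- unique(sub$run_id)
  meta_cols <- c("run_id", "habitat", "site", "fish_id", "spot_distance_um")
  meta <- unique(sub[intersect(meta_cols, names(sub))])
  wide <- matrix(NA_real_, nrow = length(ids), ncol = length(retained),
                 dimnames = list(ids, retained))
  for (e in retained) {
    se <- sub[sub$element == e, ]
    wide[se$run_id, e] <- se$ppm
  }
  if (anyNA(wide)) stop2("some samples are missing retained-element concentrations")
  totals <- rowSums(wide)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("dropping %d sample(s) with all retained elements at zero: %s",
                    sum(zero), paste(ids[zero], collapse = ", ")), call. = FALSE)
    wide <- wide[!zero, , drop = FALSE]
    ids <- ids[!zero]
    totals <- totals[!zero]
  }
  pct <- 100 * wide / totals
  out <- data.frame(run_id = ids, stringsAsFactors = FALSE)
  out <- merge(out, meta, by = "run_id", sort = FALSE)
  out <- out[match(ids, out$run_id), , drop = FALSE]
  out <- cbind(out, as.data.frame(pct, row.names = NULL))
  rownames(out) <- NULL
  attr(out, "retained_elements") <- retained
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Elements of a composition table
#' @param composition a `composition_table`.
#' @return Character vector of the element columns.
#' @export
composition_elements <- function(composition) {
  attr(composition, "retained_elements") %||%
    intersect(element_catalog()$element, names(composition))
}
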