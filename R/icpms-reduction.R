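#' Tukey outlier cleaning of a count-rate window
#'
#' Removes readings outside the far-out Tukey fences
#' `[Q1 - 3 IQR, Q3 + 3 IQR]` computed from the window's own values.
#' Quartiles use linear interpolation (`quantile` type 7). The fences are
#' two-sided: a dip in the blank is as non-physical as a spike. Applied
#' independently per isotope and per window.
#'
#' @param values numeric CPS readings of one isotope within one window
#'   (at least 4, so the quartiles are defined).
#' @return The retained values, order preserved.
#' @export
#' @examples
#' remove_outliers(c(10, 10, 10, 10, 10, 1000))
remove_outliers <- function(values) {
  if (length(values) < 4) {
    stop2("outlier cleaning needs at least 4 values in the window (quartiles undefined)")
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values[values >= q[1] - 3 * iqr & values <= q[2] + 3 * iqr]
}

window_values <- function(run, element, window) {
  if (!element %in% colnames(run$cps)) {
    stop2(sprintf("isotope `%s` not present in run %s", element, run$run_id))
  }
  keep <- run$time_s >= window[1] & run$time_s < window[2]
  run$cps[keep, element]
}

cleaned_window <- function(run, element, window, clean = TRUE) {
  v <- window_values(run, element, window)
  if (clean) v <- remove_outliers(v)
  if (!length(v)) {
    stop2(sprintf("run %s: window empty after cleaning for %s", run$run_id, element))
  }
  v
}

#' Background-subtracted net signal of one isotope
#'
#' Mean CPS over the (cleaned) ablation window minus the mean over the
#' (cleaned) blank window, floored at zero.
#'
#' @param run an `ablation_run`.
#' @param element element symbol (column of the run's CPS matrix).
#' @param clean apply [remove_outliers()] to each window first.
#' @return Net count rate, CPS.
#' @export
net_signal <- function(run, element, clean = TRUE) {
  blank <- cleaned_window(run, element, run$blank_window, clean)
  abl <- cleaned_window(run, element, run$ablation_window, clean)
  max(mean(abl) - mean(blank), 0)
}

# per-standard sensitivities, grouped into brackets of consecutive
# sequence indices (replicate standards of a bracket are averaged)
standard_brackets <- function(standards, reference, element, clean = TRUE) {
  idx <- vapply(standards, `[[`, numeric(1), "sequence_index")
  ord <- order(idx)
  standards <- standards[ord]; idx <- idx[ord]
  ref_ppm <- reference[[element]]
  if (is.null(ref_ppm) || is.na(ref_ppm)) {
    stop2(sprintf("reference material has no concentration for %s", element))
  }
  s <- vapply(standards, function(st) net_signal(st, element, clean) / ref_ppm,
              numeric(1))
  grp <- cumsum(c(TRUE, diff(idx) > 1))
  data.frame(position = tapply(idx, grp, mean),
             sensitivity = tapply(s, grp, mean))
}

#' Drift-corrected sensitivity at a sequence position
#'
#' Sensitivity (net CPS per ppm) of an isotope is measured on each NIST 612
#' standard run; replicate standards acquired back-to-back are averaged into
#' a bracket, and the sensitivity at an arbitrary acquisition index is
#' obtained by linear interpolation between the nearest bracket positions.
#' Interpolation is in acquisition order (sequence index), the only ordering
#' the session metadata records.
#'
#' @param standards list of standard `ablation_run`s of one session.
#' @param reference named vector of standard-glass concentrations (ppm).
#' @param element element symbol.
#' @param at_index sequence index at which the sensitivity is needed.
#' @param clean apply outlier cleaning.
#' @return Sensitivity in CPS per ppm.
#' @export
drift_corrected_sensitivity <- function(standards, reference, element,
                                        at_index, clean = TRUE) {
  if (length(standards) < 1) stop2("no standard runs supplied")
  idx <- vapply(standards, `[[`, numeric(1), "sequence_index")
  session <- standards[[1]]$session_id
  if (at_index < min(idx) - 0.5 || at_index > max(idx) + 0.5) {
    stop2(sprintf(
      "session %s: no standards bracketing sequence index %s", session, at_index))
  }
  br <- standard_brackets(standards, reference, element, clean)
  if (nrow(br) == 1) return(br$sensitivity[1])
  approx(br$position, br$sensitivity, xout = at_index, rule = 2)$y
}

#' Element concentrations of a sample run
#'
#' Internal/external standardization in the usual solid-sample form: with net
#' count rates R and the calcium internal standard,
#' \deqn{C_e = \frac{R_e}{R_{Ca}} \cdot \frac{S_{Ca}}{S_e} \cdot C_{Ca}}
#' where `S` are the drift-interpolated standard sensitivities at the run's
#' sequence index (equivalently
#' `C_e = (R_e/R_Ca) (R_Ca^std/R_e^std) (C_e^std/C_Ca^std) C_Ca`), and
#' `C_Ca` is the assumed otolith calcium mass fraction expressed in ppm.
#'
#' @param run a sample `ablation_run`.
#' @param standards standard runs of the same session.
#' @param reference named standard-glass concentrations (ppm), including Ca.
#' @param ca_mass_fraction otolith Ca mass fraction (default 38.8 wt%).
#' @param clean apply outlier cleaning.
#' @return Named vector of concentrations (ppm) for every non-Ca element of
#'   the run.
#' @export
concentration <- function(run, standards, reference,
                          ca_mass_fraction = otolith_ca_mass_fraction(),
                          clean = TRUE) {
  elements <- setdiff(colnames(run$cps), "Ca")
  r_ca <- net_signal(run, "Ca", clean)
  if (r_ca <= 0) {
    stop2(sprintf("run %s: zero net Ca signal, internal standard unusable", run$run_id))
  }
  c_ca <- ca_mass_fraction * 1e6
  s_ca <- drift_corrected_sensitivity(standards, reference, "Ca",
                                      run$sequence_index, clean)
  out <- vapply(elements, function(e) {
    s_e <- drift_corrected_sensitivity(standards, reference, e,
                                       run$sequence_index, clean)
    if (s_e <= 0) return(NA_real_)
    (net_signal(run, e, clean) / r_ca) * (s_ca / s_e) * c_ca
  }, numeric(1))
  out
}

#' Limit of detection of one isotope in one run
#'
#' Three standard deviations of the cleaned blank count rate, converted to
#' ppm through the same internal-standard scaling as [concentration()]:
#' `LOD_e = 3 sd(blank_e) / R_Ca * (S_Ca / S_e) * C_Ca`. The counting-time
#' correction factor of the full Longerich formulation,
#' `sqrt(1/n_blank + 1/n_ablation)`, is off by default and available via
#' `counting_time_term`.
#'
#' @inheritParams concentration
#' @param element element symbol.
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @param counting_time_term include `sqrt(1/n_B + 1/n_A)`.
#' @return LOD in ppm.
#' @export
limit_of_detection <- function(run, standards, reference, element,
                               ca_mass_fraction = otolith_ca_mass_fraction(),
                               sd_convention = c("sample", "population"),
                               counting_time_term = FALSE,
                               clean = TRUE) {
  sd_convention <- match.arg(sd_convention)
  blank <- cleaned_window(run, element, run$blank_window, clean)
  if (length(blank) < 4) stop2("cleaned blank window has fewer than 4 values")
  sdb <- sd(blank)
  if (sd_convention == "population") {
    sdb <- sdb * sqrt((length(blank) - 1) / length(blank))
  }
  s_e <- drift_corrected_sensitivity(standards, reference, element,
                                     run$sequence_index, clean)
  if (s_e <= 0) stop2(sprintf("zero sensitivity for %s, LOD undefined", element))
  s_ca <- drift_corrected_sensitivity(standards, reference, "Ca",
                                      run$sequence_index, clean)
  r_ca <- net_signal(run, "Ca", clean)
  if (r_ca <= 0) stop2(sprintf("run %s: zero net Ca signal", run$run_id))
  lod_cps <- 3 * sdb
  if (counting_time_term) {
    n_a <- length(cleaned_window(run, element, run$ablation_window, clean))
    lod_cps <- lod_cps * sqrt(1 / length(blank) + 1 / n_a)
  }
  lod_cps / r_ca * (s_ca / s_e) * (ca_mass_fraction * 1e6)
}

#' Reduce one ablation to concentrations and LOD flags
#'
#' Composes outlier cleaning, background subtraction, internal/external
#' standardization and limit-of-detection computation. Elements whose raw
#' concentration falls below their LOD are stored as 0 ppm with the
#' `below_lod` flag set.
#'
#' @inheritParams concentration
#' @param sd_convention,counting_time_term forwarded to
#'   [limit_of_detection()].
#' @return Object of class `reduced_sample`: run/session/habitat/site/fish
#'   metadata plus named vectors `element_ppm`, `lod_ppm`, `below_lod` and
#'   the pre-zeroing `raw_ppm`.
#' @export
reduce_run <- function(run, standards, reference,
                       ca_mass_fraction = otolith_ca_mass_fraction(),
                       sd_convention = "sample",
                       counting_time_term = FALSE,
                       clean = TRUE) {
  ppm <- tryCatch(
    concentration(run, standards, reference, ca_mass_fraction, clean),
    error = function(e) stop2(sprintf("run %s: %s", run$run_id, conditionMessage(e))))
  elements <- names(ppm)
  lod <- vapply(elements, function(e)
    limit_of_detection(run, standards, reference, e, ca_mass_fraction,
                       sd_convention, counting_time_term, clean), numeric(1))
  below <- is.na(ppm) | ppm < lod | ppm == 0  # zero net signal is "not detected"
  out_ppm <- ifelse(below, 0, ppm)
  structure(list(
    run_id = run$run_id, session_id = run$session_id,
    habitat = run$capture_habitat, site = run$capture_site,
    fish_id = run$fish_id, spot_distance_um = run$spot_distance_um,
    element_ppm = setNames(out_ppm, elements),
    lod_ppm = setNames(lod, elements),
    below_lod = setNames(below, elements),
    raw_ppm = ppm
  ), class = "reduced_sample")
}

#' @export
print.reduced_sample <- function(x, ...) {
  cat(sprintf("<reduced_sample> %s (%d elements, %d below LOD)\n",
              x$run_id, length(x$element_ppm), sum(x$below_lod)))
  invisible(x)
}

#' Reduce a list of runs session by session
#'
#' Splits the runs by session, uses each session's standard runs for drift
#' correction and reduces every sample run against them.
#'
#' @param runs list of `ablation_run`s (samples and standards mixed).
#' @param reference named standard-glass concentrations (ppm).
#' @param ... forwarded to [reduce_run()].
#' @return Long data.frame of class `reduced_samples` with one row per
#'   (run, element): `run_id`, `session_id`, `habitat`, `site`, `fish_id`,
#'   `spot_distance_um`, `element`, `ppm`, `lod_ppm`, `below_lod`.
#' @export
reduce_runs <- function(runs, reference, ...) {
  sessions <- split(runs, vapply(runs, `[[`, character(1), "session_id"))
  rows <- list()
  for (sess in sessions) {
    role <- vapply(sess, `[[`, character(1), "role")
    standards <- sess[role == "standard"]
    samples <- sess[role == "sample"]
    if (!length(standards)) {
      stop2(sprintf("session %s has no standard runs", sess[[1]]$session_id))
    }
    for (run in samples) {
      rs <- reduce_run(run, standards, reference, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = rs$run_id, session_id = rs$session_id,
        habitat = rs$habitat %||% NA_character_,
        site = rs$site %||% NA_character_,
        fish_id = rs$fish_id %||% NA_character_,
        spot_distance_um = rs$spot_distance_um %||% NA_real_,
        element = names(rs$element_ppm),
        ppm = unname(rs$element_ppm),
        lod_ppm = unname(rs$lod_ppm),
        below_lod = unname(rs$below_lod),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("reduced_samples", "data.frame")
  out
}

#' Reproducibility of the external standard
#'
#' Coefficient of variation (percent) of an element's apparent concentration
#' across the standard runs of a session, each standard reduced against the
#' session's mean sensitivity for that element. Used by the element-retention
#' rule (elements with standard CV of 10% or more are dropped).
#'
#' @param standards list of standard `ablation_run`s (at least 2).
#' @param reference named standard-glass concentrations (ppm).
#' @param element element symbol.
#' @param sd_convention `"sample"` (default) or `"population"`.
#' @param clean apply outlier cleaning.
#' @return CV in percent.
#' @export
standard_cv <- function(standards, reference, element,
                        sd_convention = c("sample", "population"),
                        clean = TRUE) {
  sd_convention <- match.arg(sd_convention)
  if (length(standards) < 2) stop2("standard CV needs at least 2 standard runs")
  net <- vapply(standards, function(st) net_signal(st, element, clean), numeric(1))
  s_mean <- mean(net / reference[[element]])
  if (s_mean <= 0) stop2(sprintf("mean sensitivity for %s is zero", element))
  apparent <- net / s_mean
  m <- mean(apparent)
  if (m == 0) stop2("mean apparent concentration is zero")
  s <- sd(apparent)
  if (sd_convention == "population") {
    s <- s * sqrt((length(apparent) - 1) / length(apparent))
  }
  100 * s / m
}

#' Standard CVs for a set of elements
#'
#' Convenience wrapper computing [standard_cv()] for each element over all
#' standard runs of a dataset (pooled across sessions after per-session mean
#' sensitivity would differ only through drift; pooling per session and
#' averaging is the default).
#'
#' @param runs list of `ablation_run`s; only standards are used.
#' @param reference named standard-glass concentrations.
#' @param elements element symbols (default: all non-Ca elements measured).
#' @param ... forwarded to [standard_cv()].
#' @return Named vector of CVs in percent.
#' @export
standards_cv_table <- function(runs, reference, elements = NULL, ...) {
  role <- vapply(runs, `[[`, character(1), "role")
  standards <- runs[role == "standard"]
  if (length(standards) < 2) stop2("need at least 2 standard runs")
  elements <- elements %||% setdiff(colnames(standards[[1]]$cps), "Ca")
  sessions <- split(standards, vapply(standards, `[[`, character(1), "session_id"))
  per_session <- lapply(sessions, function(st) {
    if (length(st) < 2) return(NULL)
    vapply(elements, function(e) standard_cv(st, reference, e, ...), numeric(1))
  })
  per_session <- Filter(Negate(is.null), per_session)
  if (!length(per_session)) stop2("no session has 2 or more standards")
  colMeans(do.call(rbind, per_session))
}
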