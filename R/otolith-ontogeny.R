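#' Dahl-Lea length back-calculation
#'
#' Proportional back-calculation of fish fork length at an interior otolith
#' radius: `L_i = (R_i / R_cpt) * L_cpt`, with `R_i` the otolith radius at
#' ablation spot *i* and `R_cpt`, `L_cpt` the radius and fork length at
#' capture. Vectorized over `R_i`. A radius of 0 (the otolith core) maps to
#' length 0.
#'
#' @param R_i otolith radius (um) at the spot, `0 <= R_i <= R_cpt`.
#' @param R_cpt otolith radius at capture (um), > 0.
#' @param L_cpt fork length at capture (mm), > 0.
#' @return Back-calculated fork length (mm).
#' @export
#' @examples
#' dahl_lea(1260, 2520, 224)  # 112 mm
dahl_lea <- function(R_i, R_cpt, L_cpt) {
  assert_number(R_cpt, "R_cpt", lower = 1e-9)
  assert_number(L_cpt, "L_cpt", lower = 1e-9)
  if (any(R_i < 0)) stop2("`R_i` must be >= 0")
  if (any(R_i > R_cpt)) {
    stop2("`R_i` exceeds the capture radius `R_cpt`; a spot cannot lie outside the otolith")
  }
  (R_i / R_cpt) * L_cpt
}

#' Adult otolith transect profile
#'
#' Bundles one adult's capture metadata with the percent-composition of its
#' ten core-to-edge ablation spots (0 to 1260 um in 140 um steps).
#'
#' @param fish_id,capture_site identifiers.
#' @param age_years annulus count (one annulus per year), an input.
#' @param L_cpt_mm,R_cpt_um fork length (mm) and otolith radius (um) at
#'   capture; the radius must reach past the outermost spot.
#' @param spots data.frame with `distance_um` plus element percent columns
#'   (one row per spot, strictly increasing distances 0..1260).
#' @return Object of class `adult_profile`.
#' @export
adult_profile <- function(fish_id, capture_site, age_years,
                          L_cpt_mm, R_cpt_um, spots) {
  d <- spots$distance_um
  if (is.null(d)) stop2("`spots` must have a `distance_um` column")
  if (is.unsorted(d, strictly = TRUE)) stop2("spot distances must be strictly increasing")
  expected <- seq(0, 1260, by = 140)
  if (length(d) != length(expected) || any(d != expected)) {
    stop2("spots must cover 0 to 1260 um in 140 um increments (10 spots)")
  }
  assert_number(R_cpt_um, "R_cpt_um", lower = max(d))
  assert_number(L_cpt_mm, "L_cpt_mm", lower = 1e-9)
  structure(list(fish_id = fish_id, capture_site = capture_site,
                 age_years = age_years, L_cpt_mm = L_cpt_mm,
                 R_cpt_um = R_cpt_um, spots = spots),
            class = "adult_profile")
}

#' @export
print.adult_profile <- function(x, ...) {
  lab <- if ("predicted_habitat" %in% names(x$spots)) {
    paste(substr(x$spots$predicted_habitat, 1, 1), collapse = "")
  } else "unclassified"
  cat(sprintf("<adult_profile> %s (%s, %d y, %.0f mm): %s\n",
              x$fish_id, x$capture_site, x$age_years, x$L_cpt_mm, lab))
  invisible(x)
}

#' Classify the spots of an adult transect
#'
#' Predicts the habitat of each ablation spot with a trained classifier and
#' back-calculates the fish's length at each spot with [dahl_lea()]. Spot
#' predictions are independent of one another.
#'
#' @param profile an [adult_profile()] whose spots carry the classifier's
#'   element columns.
#' @param classifier a `habitat_classifier`.
#' @return The profile with `predicted_habitat` and `length_mm` added to its
#'   spots.
#' @export
classify_transect <- function(profile, classifier) {
  missing_el <- setdiff(classifier$elements, names(profile$spots))
  if (length(missing_el)) {
    stop2(sprintf("profile %s: spot chemistry missing element(s) %s",
                  profile$fish_id, paste(missing_el, collapse = ", ")))
  }
  if (anyNA(profile$spots[classifier$elements])) {
    bad <- profile$spots$distance_um[
      rowSums(is.na(profile$spots[classifier$elements])) > 0]
    stop2(sprintf("profile %s: missing spot chemistry at distances %s um",
                  profile$fish_id, paste(bad, collapse = ", ")))
  }
  profile$spots$predicted_habitat <-
    as.character(predict(classifier, profile$spots))
  profile$spots$length_mm <-
    dahl_lea(profile$spots$distance_um, profile$R_cpt_um, profile$L_cpt_mm)
  profile
}

#' Cohort occupancy profile
#'
#' Proportion of fish carrying the mangrove signature at each transect
#' distance, with the mean back-calculated length per distance.
#'
#' @param profiles list of classified [adult_profile()]s sharing the same
#'   distance grid.
#' @param mangrove_label label counted as mangrove.
#' @return data.frame of class `occupancy_profile` with columns
#'   `distance_um`, `prop_mangrove`, `mean_length_mm`; cohort size in the
#'   `"cohort_size"` attribute.
#' @export
occupancy_profile <- function(profiles, mangrove_label = "mangrove") {
  if (!length(profiles)) stop2("`profiles` must be non-empty")
  grids <- lapply(profiles, function(p) p$spots$distance_um)
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop2("profiles use different distance grids; cannot aggregate")
  }
  if (!all(vapply(profiles, function(p)
    "predicted_habitat" %in% names(p$spots), logical(1)))) {
    stop2("all profiles must be classified first (see classify_transect)")
  }
  d <- grids[[1]]
  mang <- vapply(profiles, function(p)
    p$spots$predicted_habitat == mangrove_label, logical(length(d)))
  len <- vapply(profiles, function(p) {
    if ("length_mm" %in% names(p$spots)) p$spots$length_mm
    else dahl_lea(p$spots$distance_um, p$R_cpt_um, p$L_cpt_mm)
  }, numeric(length(d)))
  out <- data.frame(distance_um = d,
                    prop_mangrove = rowMeans(mang),
                    mean_length_mm = rowMeans(len))
  attr(out, "cohort_size") <- length(profiles)
  class(out) <- c("occupancy_profile", "data.frame")
  out
}

#' Juvenile mangrove-use call for one fish
#'
#' Two operational readings of "used mangrove as a juvenile": `"early"`
#' requires the mangrove signature at the first two spots (0 and 140 um);
#' `"throughout"` requires it at all ten spots of the juvenile transect.
#'
#' @param profile a classified [adult_profile()].
#' @param rule `"early"` or `"throughout"`.
#' @param mangrove_label label counted as mangrove.
#' @return Logical.
#' @export
juvenile_habitat_call <- function(profile, rule = c("early", "throughout"),
                                  mangrove_label = "mangrove") {
  rule <- match.arg(rule)
  ph <- profile$spots$predicted_habitat
  if (is.null(ph)) stop2("profile is not classified")
  is_m <- ph == mangrove_label
  if (rule == "early") all(is_m[profile$spots$distance_um <= 140]) else all(is_m)
}

#' Build classified profiles from pipeline tables
#'
#' Convenience assembler: joins a transect composition table (with `fish_id`
#' and `spot_distance_um` columns) to capture metadata, classifies every
#' fish's spots and returns the profile list.
#'
#' @param composition `composition_table` of the transect spots.
#' @param meta data.frame with `fish_id`, `site`, `age_years`, `L_cpt_mm`,
#'   `R_cpt_um`.
#' @param classifier a `habitat_classifier`.
#' @return List of classified `adult_profile`s, one per fish.
#' @export
build_profiles <- function(composition, meta, classifier) {
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    spots <- composition[composition$fish_id == m$fish_id, , drop = FALSE]
    spots <- spots[order(spots$spot_distance_um), , drop = FALSE]
    spots$distance_um <- spots$spot_distance_um
    pr <- adult_profile(m$fish_id, m$site, m$age_years,
                        m$L_cpt_mm, m$R_cpt_um, spots)
    classify_transect(pr, classifier)
  })
}
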