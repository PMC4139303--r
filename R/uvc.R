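#' Distance truncation of UVC records
#'
#' Keeps records whose perpendicular distance to the transect line is at most
#' `max_distance` (closed boundary: a fish at exactly 5.0 m is kept). With
#' the default 5 m on each side of a 50 m line, a truncated transect is a
#' 500 m^2 belt.
#'
#' @param records UVC data.frame with a `perp_distance_m` column.
#' @param max_distance truncation half-width in metres (default 5).
#' @return The truncated records (attributes preserved).
#' @export
truncate_uvc <- function(records, max_distance = 5) {
  keep <- records$perp_distance_m <= max_distance
  out <- records[keep, , drop = FALSE]
  attr(out, "transects") <- attr(records, "transects")
  out
}

#' Density of one transect
#'
#' Total fish counted on a truncated belt transect divided by its area.
#'
#' @param records truncated records of a single transect (possibly empty).
#' @param area belt-transect area in m^2 (default 500: 50 m x 5 m x 2 sides).
#' @return Density in fish per m^2.
#' @export
transect_density <- function(records, area = 500) {
  if (!nrow(records)) return(0)
  sum(records$count) / area
}

#' Biomass of one transect
#'
#' Length-weight conversion `W = a * FL^b` (grams from cm fork length)
#' summed over fish and divided by the transect area.
#'
#' @param records truncated records of a single transect.
#' @param lw data.frame with columns `species`, `a`, `b` (coefficients for
#'   fork length in cm, weight in g).
#' @param area belt-transect area in m^2.
#' @return Biomass in g per m^2.
#' @export
transect_biomass <- function(records, lw, area = 500) {
  if (!nrow(records)) return(0)
  i <- match(records$species, lw$species)
  if (anyNA(i)) {
    stop2("no length-weight coefficients for species: ",
          paste(unique(records$species[is.na(i)]), collapse = ", "))
  }
  sum(records$count * lw$a[i] * records$fork_length_cm^lw$b[i]) / area
}

#' Nominal length-weight coefficients for the survey species
#'
#' Synthetic nominal coefficients (`W = a FL^b`, g from cm) for the target
#' snapper and the generator's background species; replace with measured
#' regional coefficients for real surveys.
#' @return data.frame with columns `species`, `a`, `b`.
#' @export
default_lw_coefficients <- function() {
  data.frame(
    species = c("Lutjanus fulviflamma", "Chromis viridis", "Ctenochaetus striatus"),
    a = c(0.021, 0.016, 0.024),
    b = c(2.97, 3.05, 2.94),
    stringsAsFactors = FALSE
  )
}

#' Per-stratum UVC summary
#'
#' Truncates the survey, then computes for each stratum the frequency of
#' occurrence of the target species (% of transects with at least one fish),
#' its mean density and biomass (unweighted means over transects, empty
#' transects included), presence flags, and the standardized mangrove area
#' (km^2 of mangrove per km of coast).
#'
#' @param records UVC data.frame (`transect_id`, `stratum`, `species`,
#'   `count`, `fork_length_cm`, `perp_distance_m`). The full transect list
#'   (including empty transects) is taken from the records' `"transects"`
#'   attribute when present, otherwise from `transects`.
#' @param strata data.frame with `stratum`, `mangrove_area_km2`,
#'   `coast_length_km`.
#' @param species target species.
#' @param lw length-weight coefficients (see [transect_biomass()]).
#' @param max_distance truncation half-width (m).
#' @param area transect area (m^2).
#' @param transects optional data.frame `transect_id`, `stratum` enumerating
#'   all surveyed transects.
#' @return data.frame of class `stratum_summary`, one row per stratum:
#'   `stratum`, `n_transects`, `occurrence_pct`, `density_fish_m2`,
#'   `biomass_g_m2`, `mangrove_area_km2`, `coast_length_km`,
#'   `std_mangrove_km2_km`, `species_present`, `mangrove_present`.
#' @export
stratum_summary <- function(records, strata,
                            species = "Lutjanus fulviflamma",
                            lw = default_lw_coefficients(),
                            max_distance = 5, area = 500,
                            transects = NULL) {
  transects <- attr(records, "transects") %||% transects
  if (is.null(transects)) {
    transects <- unique(records[c("transect_id", "stratum")])
  }
  trunc <- truncate_uvc(records, max_distance)
  target <- trunc[trunc$species == species, , drop = FALSE]
  rows <- list()
  for (s in strata$stratum) {
    tids <- transects$transect_id[transects$stratum == s]
    if (!length(tids)) {
      warning(sprintf("stratum %s has no transects; excluded", s), call. = FALSE)
      next
    }
    per_t_density <- vapply(tids, function(tid)
      transect_density(target[target$transect_id == tid, , drop = FALSE], area),
      numeric(1))
    per_t_biomass <- vapply(tids, function(tid)
      transect_biomass(target[target$transect_id == tid, , drop = FALSE], lw, area),
      numeric(1))
    meta <- strata[strata$stratum == s, ]
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s,
      n_transects = length(tids),
      occurrence_pct = 100 * mean(per_t_density > 0),
      density_fish_m2 = mean(per_t_density),
      biomass_g_m2 = mean(per_t_biomass),
      mangrove_area_km2 = meta$mangrove_area_km2,
      coast_length_km = meta$coast_length_km,
      std_mangrove_km2_km = meta$mangrove_area_km2 / meta$coast_length_km,
      species_present = any(per_t_density > 0),
      mangrove_present = meta$mangrove_area_km2 > 0,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stratum_summary", "data.frame")
  out
}

#' Mangrove-presence / species-presence chi-square test
#'
#' Pearson chi-square without continuity correction on the 2x2 table of
#' strata cross-classified by mangrove presence and target-species presence.
#' For a perfect association the statistic equals the number of strata.
#'
#' @param summaries a [stratum_summary()] data.frame (or any data.frame with
#'   logical `mangrove_present` and `species_present` columns).
#' @return List with `chi_square`, `df` (1) and `p_value`.
#' @export
presence_chi_square <- function(summaries) {
  if (nrow(summaries) < 2) stop2("need at least 2 strata")
  tab <- table(factor(summaries$mangrove_present, levels = c(FALSE, TRUE)),
               factor(summaries$species_present, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop2("degenerate 2x2 table (a zero margin): all strata agree on one factor, ",
          "association is untestable")
  }
  n <- sum(tab)
  num <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  chi2 <- num / den
  list(chi_square = unname(chi2), df = 1L,
       p_value = unname(pchisq(chi2, df = 1, lower.tail = FALSE)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (midranks for ties), with a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors (at least 4 pairs, non-constant).
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop2("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop2("need at least 4 paired observations")
  if (all(x == x[1]) || all(y == y[1])) {
    stop2("constant vector: rank correlation undefined")
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Mangrove-abundance correlation tests
#'
#' Spearman correlations of standardized mangrove area against occurrence,
#' density and biomass across strata, plus the presence chi-square.
#'
#' @param summaries a [stratum_summary()] data.frame.
#' @return data.frame with columns `statistic`, `value`, `p`.
#' @export
mangrove_association_tests <- function(summaries) {
  x <- summaries$std_mangrove_km2_km
  sp <- function(y) spearman_correlation(x, y)
  occ <- sp(summaries$occurrence_pct)
  den <- sp(summaries$density_fish_m2)
  bio <- sp(summaries$biomass_g_m2)
  chi <- presence_chi_square(summaries)
  data.frame(
    statistic = c("spearman_occurrence", "spearman_density",
                  "spearman_biomass", "chi_square_presence"),
    value = c(occ$rho, den$rho, bio$rho, chi$chi_square),
    p = c(occ$p_value, den$p_value, bio$p_value, chi$p_value),
    stringsAsFactors = FALSE
  )
}
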