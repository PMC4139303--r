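#' Catalog of analyzed isotopes and nominal concentrations
#'
#' One row per measured isotope: the element symbol, the isotope mass used on
#' the instrument, a nominal concentration in NIST 612 reference glass (ppm)
#' and a typical reef-otolith concentration (ppm) used as the baseline of the
#' synthetic-data generator. The NIST 612 values are nominal preferred values
#' for this certified glass (Ca derived from its 11.9 wt% CaO); they can be
#' overridden wherever a `reference` argument is accepted. The reef baseline
#' is a synthetic, order-of-magnitude aragonite composition, not a measured
#' dataset.
#'
#' The row order of this table is the package's canonical element order; every
#' function that returns element lists uses it for reproducible ordering.
#'
#' @return A data.frame with columns `element`, `isotope`, `nist612_ppm`,
#'   `reef_ppm`.
#' @export
#' @examples
#' head(element_catalog())
element_catalog <- function() {
  data.frame(
    element = c("Li", "B", "Mg", "Ca", "Ti", "V", "Cr", "Mn", "Ni", "Cu",
                "Zn", "Rb", "Sr", "Mo", "Cd", "Sn", "Ba", "Pb", "Th", "U"),
    isotope = c(7L, 11L, 25L, 43L, 47L, 51L, 52L, 55L, 60L, 65L,
                66L, 85L, 88L, 95L, 111L, 117L, 138L, 208L, 232L, 238L),
    nist612_ppm = c(40.2, 34.3, 68, 85050, 44, 38.8, 36.4, 38.7, 38.8, 37.8,
                    39.1, 31.4, 78.4, 37.4, 28.3, 38.6, 39.7, 38.6, 37.8, 37.4),
    reef_ppm = c(0.2, 4, 20, 388000, 0.5, 0.05, 0.2, 1, 0.1, 0.3,
                 0.8, 0.05, 2000, 0.02, 0.01, 0.05, 2, 0.05, 0.005, 0.02),
    stringsAsFactors = FALSE
  )
}

#' NIST 612 reference concentrations
#'
#' Named numeric vector of nominal element concentrations (ppm) in the NIST
#' 612 external-standard glass, taken from [element_catalog()].
#'
#' @param elements optional character vector restricting the result.
#' @return Named numeric vector, ppm.
#' @export
nist612_reference <- function(elements = NULL) {
  cat_ <- element_catalog()
  ref <- setNames(cat_$nist612_ppm, cat_$element)
  if (is.null(elements)) return(ref)
  missing <- setdiff(elements, names(ref))
  if (length(missing)) {
    stop2("unknown element symbol(s): ", paste(missing, collapse = ", "))
  }
  ref[elements]
}

# canonical ordering used by retention / subset enumeration
canonical_elements <- function(elements) {
  ord <- element_catalog()$element
  known <- elements[elements %in% ord]
  extra <- sort(setdiff(elements, ord))
  c(ord[ord %in% known], extra)
}

#' Internal-standard calcium mass fraction of otolith aragonite
#'
#' Otoliths are calcium carbonate (aragonite); the calcium mass fraction used
#' to anchor the internal standard defaults to 38.8 wt%, the usual aragonite
#' convention. Expressed here as a mass fraction (0.388), converted to ppm
#' where needed.
#' @export
otolith_ca_mass_fraction <- function() 0.388
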