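#' Pipeline configuration
#'
#' Validates and assembles every tunable of the end-to-end chain. Defaults
#' are the study conditions: 37 mangrove and 159 reef otolith surfaces, a
#' 20-fish adult cohort of which 17 resided in mangrove over all ten
#' transect spots and 3 over the first two, a 3-fold elemental habitat
#' effect, 70%/10% element-retention thresholds, a 0.75/5000-tree forest
#' protocol (reducible), the 1260 um juvenile cutoff and the 5 m UVC
#' truncation.
#'
#' @param elements analytes simulated and screened.
#' @param effect_size habitat fold-change of the generator fingerprints.
#' @param n_mangrove,n_reef surface-characterization sample sizes.
#' @param residency_spots per-fish mangrove residency (spots from the core).
#' @param detect_threshold,cv_threshold element-retention thresholds
#'   (fraction, percent).
#' @param forest a [forest_spec()].
#' @param search_trees trees per forest during the exhaustive subset search.
#' @param max_candidates cap on the candidate list fed to the search.
#' @param juvenile_cutoff_um juvenile portion of the otolith radius.
#' @param truncation_m UVC truncation half-width.
#' @param transects_per_stratum,coupling UVC generator settings.
#' @param ca_mass_fraction internal-standard Ca mass fraction.
#' @param n_perm PERMANOVA permutations.
#' @param plan a [session_plan()].
#' @param seed master seed; all module seeds derive from it.
#' @param out_dir optional directory for CSV outputs and the run manifest.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(elements = c("Li", "B", "Mg", "Cr", "Mn", "Cu", "Zn",
                                         "Rb", "Sr", "Sn", "Ba", "U"),
                            effect_size = 3,
                            n_mangrove = 37, n_reef = 159,
                            residency_spots = c(rep(10L, 17), rep(2L, 3)),
                            detect_threshold = 0.70, cv_threshold = 10,
                            forest = forest_spec(n_trees = 5000),
                            search_trees = 500,
                            max_candidates = 12,
                            juvenile_cutoff_um = 1260,
                            truncation_m = 5,
                            transects_per_stratum = 30,
                            coupling = 1,
                            ca_mass_fraction = otolith_ca_mass_fraction(),
                            n_perm = 999,
                            plan = NULL,
                            seed = 1L,
                            out_dir = NULL) {
  assert_number(detect_threshold, "detect_threshold", lower = 0, upper = 1)
  assert_number(cv_threshold, "cv_threshold", lower = 0)
  assert_number(truncation_m, "truncation_m", lower = 0)
  assert_number(juvenile_cutoff_um, "juvenile_cutoff_um", lower = 1)
  assert_number(coupling, "coupling", lower = 0, upper = 1)
  assert_number(ca_mass_fraction, "ca_mass_fraction", lower = 1e-6, upper = 1)
  assert_number(n_perm, "n_perm", lower = 1)
  assert_number(search_trees, "search_trees", lower = 1)
  if (any(residency_spots < 0 | residency_spots > 10)) {
    stop2("`residency_spots` entries must lie in 0..10")
  }
  if (!inherits(forest, "forest_spec")) stop2("`forest` must be a forest_spec()")
  plan <- plan %||% session_plan(seed = child_seed(seed, 1))
  structure(list(
    elements = elements, effect_size = effect_size,
    n_mangrove = n_mangrove, n_reef = n_reef,
    residency_spots = as.integer(residency_spots),
    detect_threshold = detect_threshold, cv_threshold = cv_threshold,
    forest = forest, search_trees = search_trees,
    max_candidates = max_candidates,
    juvenile_cutoff_um = juvenile_cutoff_um,
    truncation_m = truncation_m,
    transects_per_stratum = transects_per_stratum,
    coupling = coupling,
    ca_mass_fraction = ca_mass_fraction,
    n_perm = n_perm, plan = plan, seed = as.integer(seed),
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full inference chain on synthetic data
#'
#' Orchestrates the modules end to end: simulate fingerprints, surface
#' sessions, adult transects and the UVC survey; reduce every ablation to
#' ppm and LODs; screen elements and percent-transform; test habitats by
#' PERMANOVA; run the exhaustive subset search and train the final
#' classifier; classify the adult transects into an occupancy profile; and
#' summarize the UVC survey against mangrove extent. Steps can be restricted
#' with `steps`; later steps pull in the earlier ones they need. When
#' `config$out_dir` is set, each step writes its CSV output plus a
#' `manifest.json` recording the package version, seed and full
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param steps subset of `c("simulate", "reduce", "select", "stats",
#'   "classify", "ontogeny", "uvc")` (default all).
#' @return List with the intermediate and final artifacts: `fingerprints`,
#'   `reduced`, `retained`, `composition`, `permanova`, `search`,
#'   `classifier`, `profiles`, `occupancy`, `summaries`, `uvc_tests`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         steps = c("simulate", "reduce", "select", "stats",
                                   "classify", "ontogeny", "uvc")) {
  steps <- match.arg(steps, several.ok = TRUE)
  need <- function(s) s %in% steps
  res <- list(config = config)
  reference <- nist612_reference(c(config$elements, "Ca"))

  res$fingerprints <- make_fingerprints(config$elements, config$effect_size,
                                        seed = child_seed(config$seed, 2))
  surface <- simulate_surface_dataset(res$fingerprints,
                                      n_mangrove = config$n_mangrove,
                                      n_reef = config$n_reef,
                                      plan = config$plan,
                                      reference = reference)
  res$surface_meta <- surface$meta

  if (need("reduce") || need("select") || need("stats") || need("classify") ||
      need("ontogeny")) {
    res$reduced <- reduce_runs(surface$runs, reference,
                               ca_mass_fraction = config$ca_mass_fraction)
    res$standard_cv <- standards_cv_table(surface$runs, reference)
  }
  if (need("select") || need("stats") || need("classify") || need("ontogeny")) {
    res$retention <- retention_report(res$reduced, res$standard_cv,
                                      config$detect_threshold, config$cv_threshold)
    res$retained <- res$retention$element[res$retention$retained]
    res$composition <- percent_transform(res$reduced, res$retained)
  }
  if (need("stats")) {
    res$permanova <- permanova_oneway(
      res$composition[, res$retained, drop = FALSE],
      res$composition$habitat, n_perm = config$n_perm,
      seed = child_seed(config$seed, 3))
    res$univariate <- univariate_permanovas(
      res$composition, n_perm = config$n_perm, seed = child_seed(config$seed, 4))
    res$pca <- arcsin_sqrt_pca(res$composition)
  }
  if (need("classify") || need("ontogeny")) {
    candidates <- res$retained
    if (length(candidates) > config$max_candidates) {
      candidates <- candidates[seq_len(config$max_candidates)]
    }
    search_spec <- config$forest
    search_spec$n_trees <- as.integer(config$search_trees)
    search_spec$seed <- child_seed(config$seed, 5)
    res$search <- exhaustive_search(res$composition,
                                    candidates = candidates, spec = search_spec)
    final_spec <- config$forest
    final_spec$seed <- child_seed(config$seed, 6)
    res$classifier <- train_forest(res$composition,
                                   elements = res$search$best$elements,
                                   spec = final_spec)
  }
  if (need("ontogeny")) {
    cohort <- simulate_adult_cohort(res$fingerprints,
                                    residency_spots = config$residency_spots,
                                    plan = config$plan, reference = reference)
    t_reduced <- reduce_runs(cohort$runs, reference,
                             ca_mass_fraction = config$ca_mass_fraction)
    res$transect_composition <- percent_transform(t_reduced, res$retained)
    res$transect_meta <- cohort$meta
    res$profiles <- build_profiles(res$transect_composition, cohort$meta,
                                   res$classifier)
    res$occupancy <- occupancy_profile(res$profiles)
    res$juvenile_calls <- data.frame(
      fish_id = vapply(res$profiles, `[[`, character(1), "fish_id"),
      early = vapply(res$profiles, juvenile_habitat_call, logical(1), rule = "early"),
      throughout = vapply(res$profiles, juvenile_habitat_call, logical(1),
                          rule = "throughout"),
      stringsAsFactors = FALSE)
  }
  if (need("uvc")) {
    res$uvc_records <- simulate_uvc_survey(
      default_strata(), coupling = config$coupling,
      transects_per_stratum = config$transects_per_stratum,
      seed = child_seed(config$seed, 7))
    res$summaries <- stratum_summary(res$uvc_records, default_strata(),
                                     max_distance = config$truncation_m)
    res$uvc_tests <- mangrove_association_tests(res$summaries)
  }
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  class(res) <- "pipeline_result"
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x)) write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wr(res$reduced, "reduced_samples.csv")
  wr(res$retention, "element_retention.csv")
  wr(as.data.frame(res$composition), "composition.csv")
  if (!is.null(res$permanova)) {
    wr(permanova_table(c(list(overall = res$permanova), res$univariate)),
       "permanova.csv")
  }
  if (!is.null(res$search)) wr(res$search$ranking, "subset_search.csv")
  if (!is.null(res$classifier)) {
    cm <- res$classifier$oob_confusion
    wr(as.data.frame(as.table(cm$counts)), "oob_confusion.csv")
  }
  wr(res$occupancy, "occupancy_profile.csv")
  wr(res$juvenile_calls, "juvenile_calls.csv")
  wr(res$summaries, "stratum_summary.csv")
  wr(res$uvc_tests, "uvc_tests.csv")
  manifest <- list(
    package = "otolithchem",
    version = as.character(utils::packageVersion("otolithchem")),
    seed = res$config$seed,
    config = res$config[setdiff(names(res$config), c("forest", "plan", "out_dir"))],
    forest = unclass(res$config$forest),
    plan = unclass(res$config$plan),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$retained)) {
    cat("  retained elements:", paste(x$retained, collapse = ", "), "\n")
  }
  if (!is.null(x$permanova)) {
    cat(sprintf("  PERMANOVA: F_%d,%d = %.2f, p = %.3g\n",
                x$permanova$df_between, x$permanova$df_within,
                x$permanova$pseudo_F, x$permanova$p_value))
  }
  if (!is.null(x$classifier)) {
    cat(sprintf("  classifier: %s (OOB overall %.1f%%)\n",
                paste(x$classifier$elements, collapse = "+"),
                x$classifier$oob_confusion$overall_pct))
  }
  if (!is.null(x$occupancy)) {
    late <- x$occupancy$prop_mangrove[x$occupancy$distance_um >= 280]
    cat(sprintf("  occupancy: %.0f%% mangrove at 0-140 um, %.0f%% from 280 um\n",
                100 * mean(x$occupancy$prop_mangrove[1:2]), 100 * mean(late)))
  }
  if (!is.null(x$uvc_tests)) {
    rho <- x$uvc_tests$value[x$uvc_tests$statistic == "spearman_density"]
    cat(sprintf("  UVC: Spearman rho(density) = %.2f\n", rho))
  }
  invisible(x)
}
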