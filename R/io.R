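#' Write ablation runs to a long-format session CSV
#'
#' One row per (run, element, reading): `run_id`, `role`, `session_id`,
#' `sequence_index`, `time_s`, `element`, `cps`. Run-level capture metadata
#' goes to a companion metadata table (see [runs_metadata()]).
#'
#' @param runs list of `ablation_run`s.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_session_csv <- function(runs, path) {
  rows <- lapply(runs, function(r) {
    data.frame(run_id = r$run_id, role = r$role, session_id = r$session_id,
               sequence_index = r$sequence_index,
               time_s = rep(r$time_s, times = ncol(r$cps)),
               element = rep(colnames(r$cps), each = nrow(r$cps)),
               cps = as.vector(r$cps),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run-level metadata table
#'
#' @param runs list of `ablation_run`s.
#' @return data.frame: `run_id`, `habitat`, `site`, `fish_id`,
#'   `spot_distance_um`.
#' @export
runs_metadata <- function(runs) {
  do.call(rbind, lapply(runs, function(r) data.frame(
    run_id = r$run_id,
    habitat = r$capture_habitat %||% NA_character_,
    site = r$capture_site %||% NA_character_,
    fish_id = r$fish_id %||% NA_character_,
    spot_distance_um = r$spot_distance_um %||% NA_real_,
    stringsAsFactors = FALSE)))
}

#' Read ablation runs from a long-format session CSV
#'
#' Inverse of [write_session_csv()]. Readings must form a complete
#' time-by-element grid per run.
#'
#' @param path session CSV path.
#' @param metadata optional metadata data.frame or CSV path (`run_id`,
#'   `habitat`, `site`, `fish_id`, `spot_distance_um`).
#' @param blank_window,ablation_window window definitions in seconds.
#' @return List of `ablation_run`s in acquisition order.
#' @export
read_session_csv <- function(path, metadata = NULL,
                             blank_window = c(0, 30),
                             ablation_window = c(30, 120)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "role", "session_id", "sequence_index",
            "time_s", "element", "cps")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop2("session CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.character(metadata)) metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  runs <- lapply(split(df, df$run_id), function(d) {
    elements <- unique(d$element)
    times <- sort(unique(d$time_s))
    cps <- matrix(NA_real_, length(times), length(elements),
                  dimnames = list(NULL, elements))
    for (e in elements) {
      de <- d[d$element == e, ]
      cps[match(de$time_s, times), e] <- de$cps
    }
    if (anyNA(cps)) stop2(sprintf("run %s: incomplete time-by-element grid", d$run_id[1]))
    meta <- if (!is.null(metadata)) metadata[metadata$run_id == d$run_id[1], ] else NULL
    pick <- function(col, default) {
      if (!is.null(meta) && nrow(meta) == 1 && col %in% names(meta)) meta[[col]] else default
    }
    structure(list(
      run_id = d$run_id[1], role = d$role[1], session_id = d$session_id[1],
      sequence_index = d$sequence_index[1],
      time_s = times, cps = cps,
      blank_window = blank_window, ablation_window = ablation_window,
      capture_habitat = pick("habitat", NA_character_),
      capture_site = pick("site", NA_character_),
      fish_id = pick("fish_id", NA_character_),
      spot_distance_um = pick("spot_distance_um", NA_real_),
      truth = NULL
    ), class = "ablation_run")
  })
  ord <- order(vapply(runs, `[[`, character(1), "session_id"),
               vapply(runs, `[[`, numeric(1), "sequence_index"))
  unname(runs[ord])
}
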