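#' Write and read recordings, schedules and event tables
#'
#' Plain-text interchange: the current trace as a single-column CSV with a
#' JSON sidecar carrying the sampling rate and stimulus markers; schedules
#' and event tables as CSV.
#'
#' @param rec a `sweep_trace`.
#' @param path output path for the trace CSV; the sidecar gets the same
#'   path with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(rec, path) {
  stopifnot(inherits(rec, "sweep_trace"))
  readr::write_csv(tibble::tibble(current_pa = rec$current_pa), path)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(
    rate_hz = rec$rate_hz,
    duration_ms = rec$duration_ms,
    stim = rec$schedule[, c("target_id", "rep", "pulse", "time_ms")]
  ), side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)$current_pa
  side <- sub("\\.csv$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  structure(list(current_pa = tr, rate_hz = meta$rate_hz,
                 schedule = tibble::as_tibble(meta$stim),
                 events = NULL, duration_ms = meta$duration_ms),
            class = "sweep_trace")
}

#' @rdname write_trace_csv
#' @param events an EPSC event table.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(tibble::as_tibble(events), path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_events_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname write_trace_csv
#' @param schedule a `stim_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  readr::write_csv(tibble::as_tibble(schedule), path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_schedule_csv <- function(path) {
  s <- readr::read_csv(path, show_col_types = FALSE)
  structure(tibble::new_tibble(s, class = "stim_schedule"),
            n_targets = length(unique(s$target_id)),
            duration_ms = max(s$time_ms) + 1000)
}

#' Apply manual-curation overrides to connectivity calls
#'
#' Mirrors the human-in-the-loop resolution of ambiguous calls: a labels
#' table (`target_id`, `connected`) overrides the model decision for the
#' listed targets.
#'
#' @param calls tibble of connectivity calls with `target_id` and
#'   `connected`.
#' @param labels override tibble (`target_id`, `connected`).
#' @return `calls` with overridden decisions and an `overridden` column.
#' @export
apply_manual_overrides <- function(calls, labels) {
  stopifnot(all(c("target_id", "connected") %in% names(labels)))
  idx <- match(calls$target_id, labels$target_id)
  hit <- !is.na(idx)
  calls$overridden <- hit
  calls$connected[hit] <- labels$connected[idx[hit]]
  calls
}
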