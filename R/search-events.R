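# The pitch-metric search-event detector: benthic-foraging seals invert into
# a head-down posture to search the sea floor, so a sustained high pitch at
# depth is the operational signature of searching. Because descent also
# starts near-vertical, a depth gate excludes the top few metres of the
# water column.

#' Detect head-down search events
#'
#' A search event is a maximal contiguous run of samples with
#' `pitch >= pitch_threshold` AND `depth <= depth_threshold` (both
#' comparisons inclusive). By default every run counts, with no minimum
#' duration; `min_event_s` is an escape hatch for noisy records.
#'
#' @param data Data frame with aligned `pitch` (deg, positive head-down) and
#'   `depth` (m, negative below surface) columns; a `time` column (s) is used
#'   for event timing when present, otherwise sample index / `fs`.
#' @param fs Sampling rate (Hz).
#' @param pitch_threshold Minimum pitch, degrees (default 70).
#' @param depth_threshold Maximum depth, metres (default -3; i.e. at least
#'   3 m below the surface).
#' @param min_event_s Minimum event duration in seconds (default 0).
#' @param flip_pitch Set `TRUE` for tags mounted backwards (negates pitch
#'   before thresholding).
#' @return Tibble of events: `start, end` (sample indices), `start_s, end_s`
#'   (seconds), `peak_pitch` (deg), `mean_depth` (m).
#' @export
detect_search_events <- function(data, fs, pitch_threshold = 70,
                                 depth_threshold = -3, min_event_s = 0,
                                 flip_pitch = FALSE) {
  check_columns(data, c("pitch", "depth"), "detector input")
  pitch <- if (flip_pitch) -data$pitch else data$pitch
  depth <- data$depth
  if (length(pitch) != length(depth)) {
    abort("pitch and depth must share the same time base.",
          class = "sealsearch_alignment_error")
  }
  time <- if ("time" %in% names(data)) data$time else (seq_along(pitch) - 1) / fs
  mask <- !is.na(pitch) & pitch >= pitch_threshold & depth <= depth_threshold
  runs <- true_runs(mask)
  if (nrow(runs) == 0) {
    return(tibble(start = integer(0), end = integer(0),
                  start_s = numeric(0), end_s = numeric(0),
                  peak_pitch = numeric(0), mean_depth = numeric(0)))
  }
  runs <- runs[(runs$end - runs$start + 1) / fs >= min_event_s, ]
  purrr::pmap_dfr(runs, function(start, end) {
    idx <- start:end
    tibble(start = start, end = end,
           start_s = time[start], end_s = time[end],
           peak_pitch = max(pitch[idx]), mean_depth = mean(depth[idx]))
  })
}

#' Total search time within a dive
#'
#' Sum of event durations and its share of the dive duration — a per-dive
#' measure of search effort.
#'
#' @param events Event tibble from [detect_search_events()] (one dive).
#' @param dive_start_s,dive_end_s Dive bounds in seconds.
#' @param fs Sampling rate (Hz); each event spans
#'   `end_s - start_s + 1/fs` seconds (inclusive sample bounds).
#' @return List `search_time_s`, `search_proportion`.
#' @export
search_time <- function(events, dive_start_s, dive_end_s, fs) {
  duration <- dive_end_s - dive_start_s + 1 / fs
  if (duration <= 0) abort("dive has non-positive duration.",
                           class = "sealsearch_domain_error")
  if (nrow(events) == 0) return(list(search_time_s = 0, search_proportion = 0))
  if (any(events$start_s < dive_start_s - 1e-9) ||
      any(events$end_s > dive_end_s + 1e-9)) {
    abort("event lies outside the dive bounds.",
          class = "sealsearch_consistency_error")
  }
  st <- sum(events$end_s - events$start_s + 1 / fs)
  list(search_time_s = st, search_proportion = st / duration)
}

#' Classify a dive as searching/foraging
#'
#' A dive is a searching (foraging) dive when it contains at least one
#' search event.
#'
#' @param n_events Number of search events on the dive (vectorised).
#' @return Logical flag(s).
#' @export
classify_dive <- function(n_events) {
  n_events >= 1
}

#' Write search events to CSV
#' @param events Event tibble (with `dive_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  cols <- intersect(c("dive_id", "start_s", "end_s", "peak_pitch", "mean_depth"),
                    names(events))
  readr::write_csv(events[cols], path, progress = FALSE)
  invisible(path)
}
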