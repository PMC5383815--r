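# Dive detection from the depth channel and per-dive descriptors.

#' Detect dives in a depth record
#'
#' A dive is a maximal run of samples deeper than `dive_threshold_m`,
#' extended outwards to the adjacent surface crossings (the nearest samples
#' at or above `surface_m`), and kept when it lasts at least
#' `min_duration_s`. Runs sharing a submerged stretch merge into one dive.
#'
#' @param depth Numeric depth vector (m, negative below surface).
#' @param fs Sampling rate (Hz).
#' @param dive_threshold_m Depth a run must exceed to count as a dive
#'   (default -1.5 m).
#' @param min_duration_s Minimum dive duration (default 8 s).
#' @param surface_m Depth regarded as "at the surface" when extending runs
#'   (default -0.25 m).
#' @return Tibble `start, end` (sample indices, inclusive), non-overlapping
#'   and ordered.
#' @export
detect_dives <- function(depth, fs, dive_threshold_m = -1.5,
                         min_duration_s = 8, surface_m = -0.25) {
  n <- length(depth)
  if (n == 0) return(tibble(start = integer(0), end = integer(0)))
  runs <- true_runs(depth < dive_threshold_m)
  if (nrow(runs) == 0) return(tibble(start = integer(0), end = integer(0)))
  at_surface <- depth >= surface_m
  # extend each run to the samples adjacent to the nearest surface crossing
  surf_idx <- which(at_surface)
  ext <- purrr::pmap_dfr(runs, function(start, end) {
    prev_surf <- surf_idx[surf_idx < start]
    next_surf <- surf_idx[surf_idx > end]
    tibble(
      start = if (length(prev_surf)) max(prev_surf) + 1L else 1L,
      end = if (length(next_surf)) min(next_surf) - 1L else n
    )
  })
  # runs within the same submerged stretch got identical bounds; merge them
  ext <- dplyr::distinct(ext)
  keep <- (ext$end - ext$start + 1L) / fs >= min_duration_s
  ext[keep, ]
}

#' Bottom time of a dive
#'
#' Time spent at more than 80% of the dive's maximum depth, and its share of
#' dive duration. Uses depth samples directly (no crossing interpolation), so
#' results carry a one-sample tolerance.
#'
#' @param depth_segment Depth samples of one dive (m, negative).
#' @param fs Sampling rate (Hz).
#' @param max_depth Maximum (most negative) depth of the dive; defaults to
#'   `min(depth_segment)`.
#' @param frac Bottom fraction of maximum depth (default 0.8).
#' @return List `bottom_time_s`, `bottom_pct`.
#' @export
bottom_time <- function(depth_segment, fs, max_depth = min(depth_segment),
                        frac = 0.8) {
  n <- length(depth_segment)
  if (n == 0) abort("zero-duration dive segment.", class = "sealsearch_domain_error")
  in_bottom <- abs(depth_segment) > frac * abs(max_depth)
  bt <- sum(in_bottom) / fs
  list(bottom_time_s = bt, bottom_pct = 100 * sum(in_bottom) / n)
}

#' Assign trip identifiers to dives
#'
#' Consecutive dives separated by a surface/haul-out gap of at least
#' `gap_min` minutes start a new trip.
#'
#' @param dives Dive tibble with `start_s`, `end_s` (one seal).
#' @param gap_min Gap (minutes) delimiting trips (default 30).
#' @return Integer trip ids, one per dive.
#' @export
assign_trips <- function(dives, gap_min = 30) {
  if (nrow(dives) == 0) return(integer(0))
  gaps <- c(0, dives$start_s[-1] - dives$end_s[-nrow(dives)])
  cumsum(gaps >= gap_min * 60) + 1L
}

#' Summarize one dive
#'
#' Fills the descriptor fields for a single dive: timing, maximum depth,
#' bottom time, mean ODBA and gyroscope RMS. Search-event fields are added by
#' [detect_search_events()] / [summarize_dives()].
#'
#' @param series A kinematics-augmented series from [derive_kinematics()].
#' @param start,end Dive bounds (sample indices) from [detect_dives()].
#' @return One-row tibble of dive descriptors.
#' @export
summarize_dive <- function(series, start, end) {
  n <- nrow(series)
  if (start < 1 || end > n || end <= start) {
    abort(sprintf("dive bounds [%d, %d] outside series of length %d", start, end, n),
          class = "sealsearch_index_error")
  }
  fs <- sampling_rate(series)
  seg <- series[start:end, ]
  bt <- bottom_time(seg$depth, fs)
  tibble(
    start_s = series$time[start],
    end_s = series$time[end],
    max_depth = min(seg$depth),
    duration_s = (end - start + 1) / fs,
    bottom_time_s = bt$bottom_time_s,
    bottom_pct = bt$bottom_pct,
    mean_odba = mean(seg$odba),
    gyro_rms = gyro_rms(seg)
  )
}

#' Summarize every dive of a deployment record
#'
#' Runs [detect_dives()], summarizes each dive, detects search events inside
#' each dive and attaches trip ids and the searching classification.
#'
#' @param series A kinematics-augmented series from [derive_kinematics()].
#' @param dive_threshold_m,min_duration_s Passed to [detect_dives()].
#' @param pitch_threshold,depth_threshold,min_event_s Passed to
#'   [detect_search_events()].
#' @param trip_gap_min Passed to [assign_trips()].
#' @return List with `dives` (one row per dive) and `events` (one row per
#'   search event).
#' @export
summarize_dives <- function(series, dive_threshold_m = -1.5, min_duration_s = 8,
                            pitch_threshold = 70, depth_threshold = -3,
                            min_event_s = 0, trip_gap_min = 30) {
  fs <- sampling_rate(series)
  seal <- attr(series, "seal_id") %||% "seal"
  bounds <- detect_dives(series$depth, fs, dive_threshold_m, min_duration_s)
  if (nrow(bounds) == 0) {
    return(list(dives = tibble(), events = tibble()))
  }
  dives <- purrr::pmap_dfr(bounds, function(start, end) {
    summarize_dive(series, start, end)
  })
  dives <- mutate(dives,
                  dive_id = paste0(seal, "-d", sprintf("%04d", row_number())),
                  seal_id = seal, .before = 1)
  events <- purrr::pmap_dfr(cbind(bounds, dive_id = dives$dive_id),
    function(start, end, dive_id) {
      ev <- detect_search_events(series[start:end, c("pitch", "depth", "time")],
                                 fs = fs, pitch_threshold = pitch_threshold,
                                 depth_threshold = depth_threshold,
                                 min_event_s = min_event_s)
      if (nrow(ev) > 0) ev$dive_id <- dive_id
      ev
    })
  per_dive <- if (nrow(events) > 0) {
    events %>%
      group_by(.data$dive_id) %>%
      summarise(n_search_events = dplyr::n(),
                search_time_s = sum(.data$end_s - .data$start_s + 1 / fs),
                .groups = "drop")
  } else {
    tibble(dive_id = character(0), n_search_events = integer(0),
           search_time_s = numeric(0))
  }
  dives <- dives %>%
    left_join(per_dive, by = "dive_id") %>%
    mutate(n_search_events = dplyr::coalesce(.data$n_search_events, 0L),
           search_time_s = dplyr::coalesce(.data$search_time_s, 0),
           searching = .data$n_search_events >= 1L)
  dives$trip_id <- assign_trips(dives, trip_gap_min)
  dives <- dplyr::relocate(dives, "trip_id", .after = "seal_id")
  list(dives = dives, events = events)
}

#' Per-seal deployment summary
#'
#' Mean and standard deviation of maximum dive depth, dive duration, bottom
#' percentage and (when covariates are joined) dive ratio, plus the mean
#' bathymetry of searching dives ("search depth") — the standard per-animal
#' summary table for a biologging deployment.
#'
#' @param dives Dive tibble (possibly several seals).
#' @return One row per seal. For a single dive, standard deviations are
#'   reported as 0 by convention and flagged by `n_dives = 1`.
#' @export
summarize_deployment <- function(dives) {
  check_columns(dives, c("seal_id", "max_depth", "duration_s", "bottom_pct",
                         "searching"), "dive table")
  sd0 <- function(x) if (length(x) <= 1) 0 else sd(x)
  dives %>%
    group_by(.data$seal_id) %>%
    summarise(
      n_dives = dplyr::n(),
      n_trips = if ("trip_id" %in% names(dives)) dplyr::n_distinct(.data$trip_id) else NA_integer_,
      depth_mean = mean(abs(.data$max_depth)),
      depth_sd = sd0(abs(.data$max_depth)),
      duration_min_mean = mean(.data$duration_s) / 60,
      duration_min_sd = sd0(.data$duration_s / 60),
      bottom_pct_mean = mean(.data$bottom_pct),
      dive_ratio_mean = if ("dive_ratio" %in% names(dives)) mean(.data$dive_ratio) else NA_real_,
      dive_ratio_sd = if ("dive_ratio" %in% names(dives)) sd0(.data$dive_ratio) else NA_real_,
      search_depth_mean = if ("bathymetry_m" %in% names(dives))
        mean(abs(.data$bathymetry_m[.data$searching])) else NA_real_,
      p_searching = mean(.data$searching),
      .groups = "drop"
    )
}
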