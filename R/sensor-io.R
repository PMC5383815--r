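# Reading, writing and validating pipeline artefacts: raw sensor streams,
# GPS tracks and per-dive tables. Depth is stored internally as NEGATIVE
# metres below the surface so threshold rules read in their natural units.

SENSOR_COLS <- c("time", "ax", "ay", "az", "mx", "my", "mz",
                 "gx", "gy", "gz", "depth")

#' Construct and validate a sensor series
#'
#' A sensor series is a tibble of uniformly sampled channels from an
#' animal-borne tag: tri-axial accelerometer (`ax, ay, az`, in g), tri-axial
#' magnetometer (`mx, my, mz`, arbitrary consistent units), tri-axial
#' gyroscope (`gx, gy, gz`, deg/s) and pressure-derived depth (`depth`, m,
#' negative below the surface). `time` is seconds since the series origin.
#'
#' @param data Data frame with columns `time, ax, ay, az, mx, my, mz, gx, gy,
#'   gz, depth`.
#' @param fs Sampling rate in Hz (> 0).
#' @param seal_id Identifier of the animal carrying the tag.
#' @param t0 Series origin (POSIXct, UTC); defaults to the epoch.
#' @param surface_bound Largest tolerated positive depth (surface noise), m.
#' @return A `sensor_series` tibble (the input columns plus attributes
#'   `fs`, `seal_id`, `t0`).
#' @export
sensor_series <- function(data, fs, seal_id = "seal", t0 = as.POSIXct(0, origin = "1970-01-01", tz = "UTC"),
                          surface_bound = 0.5) {
  data <- as_tibble(data)
  check_columns(data, SENSOR_COLS, "sensor series")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive sampling rate in Hz.")
  }
  n <- nrow(data)
  if (n >= 2) {
    dt <- diff(data$time)
    if (any(abs(dt - 1 / fs) > 0.5 / fs)) {
      bad <- which(abs(dt - 1 / fs) > 0.5 / fs)[1]
      abort(sprintf(
        "non-uniform sampling: gap of %.4f s between rows %d and %d (expected %.4f s); split gapped records into separate series",
        dt[bad], bad, bad + 1, 1 / fs), class = "sealsearch_sampling_error")
    }
  }
  if (any(data$depth > surface_bound)) {
    abort(sprintf(
      "depth exceeds the surface-noise bound of +%.2f m; is the record positive-down? (use depth_positive_down = TRUE when reading)",
      surface_bound), class = "sealsearch_depth_error")
  }
  structure(data,
            class = c("sensor_series", class(data)),
            fs = fs, seal_id = seal_id, t0 = t0)
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series> seal %s, %d samples @ %g Hz (%.1f s)\n",
              attr(x, "seal_id"), nrow(x), attr(x, "fs"),
              nrow(x) / attr(x, "fs")))
  NextMethod()
}

#' Sampling rate of a sensor series
#' @param series A `sensor_series`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(series) attr(series, "fs")

#' Normalize the depth sign convention
#'
#' Internally depth is negative below the surface. Records logged
#' positive-down are flipped; the operation is idempotent (a record already
#' negative-down is returned unchanged).
#'
#' @param depth Numeric depth vector.
#' @param positive_down Was the record logged with positive values below the
#'   surface?
#' @return Depth with negative values below the surface.
#' @export
normalize_depth_sign <- function(depth, positive_down = FALSE) {
  if (!positive_down) return(depth)
  # only flip if the record really is positive-down; keeps the op idempotent
  if (sum(depth > 0, na.rm = TRUE) >= sum(depth < 0, na.rm = TRUE)) -depth else depth
}

#' Read a sensor CSV
#'
#' Expects comma-separated text with header columns
#' `time, ax, ay, az, mx, my, mz, gx, gy, gz, depth`.
#'
#' @param path File path.
#' @param fs_expected Sampling rate the record claims (Hz); timestamps are
#'   validated against it (tolerance half a sample period).
#' @param depth_positive_down Input dialect: `TRUE` if depth was logged
#'   positive below the surface.
#' @inheritParams sensor_series
#' @return A validated [sensor_series()].
#' @export
read_sensor_csv <- function(path, fs_expected, seal_id = "seal",
                            depth_positive_down = FALSE, surface_bound = 0.5) {
  data <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE),
    error = function(e) abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
                              class = "sealsearch_parse_error"))
  check_columns(data, SENSOR_COLS, sprintf("sensor file %s", path))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed row(s) in %s: first at line %d (%s)",
                  path, probs$row[1] + 1L, probs$expected[1]),
          class = "sealsearch_parse_error")
  }
  data$depth <- normalize_depth_sign(data$depth, depth_positive_down)
  sensor_series(data, fs = fs_expected, seal_id = seal_id,
                surface_bound = surface_bound)
}

#' Write a sensor series to CSV
#' @param series A [sensor_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(series, path) {
  readr::write_csv(as_tibble(series)[SENSOR_COLS], path, progress = FALSE)
  invisible(path)
}

#' Read / write a GPS track CSV (`time, x, y`; planar metres)
#' @param path File path.
#' @param seal_id Animal identifier attached to the returned track.
#' @return `read_gps_csv()`: a tibble `time, x, y` with strictly increasing
#'   time; `write_gps_csv()`: `path`, invisibly.
#' @export
read_gps_csv <- function(path, seal_id = "seal") {
  data <- readr::read_csv(path, col_types = "ddd", progress = FALSE)
  check_columns(data, c("time", "x", "y"), "GPS track")
  if (is.unsorted(data$time, strictly = TRUE)) {
    abort("GPS timestamps must be strictly increasing.",
          class = "sealsearch_schema_error")
  }
  structure(as_tibble(data), seal_id = seal_id)
}

#' @rdname read_gps_csv
#' @param track A GPS track tibble.
#' @export
write_gps_csv <- function(track, path) {
  readr::write_csv(as_tibble(track)[c("time", "x", "y")], path, progress = FALSE)
  invisible(path)
}

# Columns a dive table must carry; habitat is a category string, everything
# else numeric/logical.
DIVE_NUMERIC_COLS <- c("start_s", "end_s", "max_depth", "duration_s",
                       "bottom_time_s", "bottom_pct", "mean_odba", "gyro_rms",
                       "n_search_events", "search_time_s")
DIVE_ID_COLS <- c("dive_id", "seal_id", "trip_id")

#' Write and read per-dive tables
#'
#' Per-dive tables carry one row per dive with timing, depth, behaviour
#' metrics, search-event counts and (optionally) environmental covariates.
#' All numeric fields round-trip losslessly; habitat is stored as a category
#' string.
#'
#' @param dives Dive tibble.
#' @param path File path.
#' @return `read_dive_table()` returns the dive tibble; `write_dive_table()`
#'   returns `path` invisibly.
#' @export
write_dive_table <- function(dives, path) {
  check_columns(dives, c(DIVE_ID_COLS, DIVE_NUMERIC_COLS, "searching"), "dive table")
  readr::write_csv(dives, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dive_table
#' @export
read_dive_table <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  check_columns(data, c(DIVE_ID_COLS, DIVE_NUMERIC_COLS, "searching"), "dive table")
  if (nrow(data) > 0) {
    bad <- DIVE_NUMERIC_COLS[!vapply(data[DIVE_NUMERIC_COLS], is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort(sprintf("non-numeric values in dive-table column(s): %s",
                    paste(bad, collapse = ", ")),
            class = "sealsearch_schema_error")
    }
    if (!is.logical(data$searching)) data$searching <- as.logical(data$searching)
  }
  as_tibble(data)
}

#' Align instrument clocks by the deepest dive of each trip
#'
#' Instruments on the same animal drift apart; the deepest point of each
#' foraging trip is a sharp, shared landmark. For every trip the offset is the
#' time of the deepest sample on the reference instrument minus the time of
#' the deepest sample on the other instrument: adding the offset to the other
#' instrument's clock makes the deepest-dive times coincide.
#'
#' @param reference Tibble `time, depth` from the reference instrument.
#' @param other Tibble `time, depth` from the instrument to be aligned.
#' @param trip_bounds Tibble `trip_id, start, end` (seconds, on each
#'   instrument's own clock) delimiting trips; the same bounds are applied to
#'   both records.
#' @param dive_threshold_m Minimum (most negative) depth a trip must reach to
#'   contain a usable dive.
#' @return Tibble `trip_id, offset_s` — seconds to add to `other`'s clock.
#' @export
align_clocks <- function(reference, other, trip_bounds,
                         dive_threshold_m = -1.5) {
  check_columns(reference, c("time", "depth"), "reference series")
  check_columns(other, c("time", "depth"), "other series")
  check_columns(trip_bounds, c("trip_id", "start", "end"), "trip bounds")
  deepest_time <- function(series, lo, hi) {
    sel <- series$time >= lo & series$time <= hi
    if (!any(sel) || min(series$depth[sel]) > dive_threshold_m) return(NA_real_)
    series$time[sel][which.min(series$depth[sel])]
  }
  out <- purrr::pmap_dfr(trip_bounds, function(trip_id, start, end, ...) {
    t_ref <- deepest_time(reference, start, end)
    t_oth <- deepest_time(other, start, end)
    if (is.na(t_ref) || is.na(t_oth)) {
      abort(sprintf("trip %s contains no dive below %.1f m on both instruments",
                    trip_id, dive_threshold_m),
            class = "sealsearch_alignment_error")
    }
    tibble(trip_id = trip_id, offset_s = t_ref - t_oth)
  })
  out
}

#' Write a posterior summary table to CSV
#' @param fit A [fit_search_model()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(fit, path) {
  readr::write_csv(tidy(fit), path, progress = FALSE)
  invisible(path)
}
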