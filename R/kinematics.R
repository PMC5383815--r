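# Attitude and body-motion metrics from raw tri-axial channels.
#
# Conventions: accelerometer in g; at rest the static vector has norm 1 and
# points along +Z when the animal is level. Positive pitch = head-down.
# Angles in degrees. The body frame is de-rotated roll first, then pitch
# (two-step Euler de-rotation, not a quaternion fusion).

#' Separate static (gravity) and dynamic acceleration
#'
#' A centred moving average over `window_s` seconds estimates the
#' low-frequency gravity component on each axis; the residual is the dynamic
#' (movement) component. Edges use shrinking windows, so no data is invented
#' and `static + dynamic` reconstructs the raw signal exactly everywhere.
#'
#' @param acc Data frame with accelerometer columns `ax, ay, az` (g), e.g. a
#'   [sensor_series()].
#' @param fs Sampling rate (Hz).
#' @param window_s Moving-average window length in seconds (default 2).
#' @return A tibble with static (`sx, sy, sz`) and dynamic (`dx, dy, dz`)
#'   components, one row per input sample.
#' @export
separate_gravity <- function(acc, fs, window_s = 2) {
  check_columns(acc, c("ax", "ay", "az"), "acceleration")
  if (window_s * fs < 1) abort("`window_s * fs` must be at least one sample.")
  n <- nrow(acc)
  h <- floor(window_s * fs / 2)
  if (n < 2 * h + 1) {
    warn(sprintf("series (%d samples) shorter than one %g s window; all windows are edge-truncated",
                 n, window_s))
  }
  sx <- moving_average(acc$ax, h)
  sy <- moving_average(acc$ay, h)
  sz <- moving_average(acc$az, h)
  tibble(sx = sx, sy = sy, sz = sz,
         dx = acc$ax - sx, dy = acc$ay - sy, dz = acc$az - sz)
}

#' Overall dynamic body acceleration (ODBA)
#'
#' Per-sample sum of the absolute dynamic accelerations on the three axes —
#' a proxy for body motion and energetic effort.
#'
#' @param dynamic_acc Data frame with dynamic components `dx, dy, dz` (g),
#'   e.g. from [separate_gravity()].
#' @return Numeric vector of ODBA (g, >= 0), one value per sample.
#' @export
odba <- function(dynamic_acc) {
  check_columns(dynamic_acc, c("dx", "dy", "dz"), "dynamic acceleration")
  abs(dynamic_acc$dx) + abs(dynamic_acc$dy) + abs(dynamic_acc$dz)
}

#' Attitude (pitch, roll, yaw) from static acceleration and magnetometer
#'
#' Roll is `atan2(Ya, Za)`; after de-rotating roll, pitch is
#' `atan(-Xa / Z')` with `Z' = Ya sin(roll) + Za cos(roll)`; the magnetometer
#' is de-rotated by roll then pitch and yaw is `atan2(Ym', Xm')`. Positive
#' pitch is head-down. Samples whose static norm falls below `norm_floor`
#' (e.g. during violent manoeuvres where the moving average no longer
#' isolates gravity) are marked invalid (`NA`).
#'
#' @param static_acc Data frame with static components `sx, sy, sz` (g).
#' @param mag Data frame with magnetometer columns `mx, my, mz`, or `NULL` to
#'   skip yaw.
#' @param norm_floor Minimum static-acceleration norm (g) for a valid
#'   attitude sample.
#' @return Tibble `pitch, roll, yaw` in degrees (`pitch` in \[-90, 90\],
#'   `roll`/`yaw` in (-180, 180\]) plus `valid`.
#' @export
attitude <- function(static_acc, mag = NULL, norm_floor = 0.3) {
  check_columns(static_acc, c("sx", "sy", "sz"), "static acceleration")
  xa <- static_acc$sx; ya <- static_acc$sy; za <- static_acc$sz
  nrm <- sqrt(xa^2 + ya^2 + za^2)
  valid <- is.finite(nrm) & nrm >= norm_floor
  roll <- atan2(ya, za)
  zp <- ya * sin(roll) + za * cos(roll)
  pitch <- atan2(-xa, zp)            # zp >= 0 by construction, so result is atan(-xa/zp)
  yaw <- rep(NA_real_, length(xa))
  if (!is.null(mag)) {
    check_columns(mag, c("mx", "my", "mz"), "magnetometer")
    # de-rotate roll about X, then pitch about Y
    m1x <- mag$mx
    m1y <- mag$my * cos(roll) - mag$mz * sin(roll)
    m1z <- mag$my * sin(roll) + mag$mz * cos(roll)
    m2x <- m1x * cos(pitch) + m1z * sin(pitch)
    m2y <- m1y
    yaw <- atan2(m2y, m2x)
  }
  out <- tibble(pitch = rad2deg(pitch), roll = rad2deg(roll),
                yaw = rad2deg(yaw), valid = valid)
  out$pitch[!valid] <- NA_real_
  out$roll[!valid] <- NA_real_
  out$yaw[!valid] <- NA_real_
  out
}

#' Body rotation matrix for given attitude angles
#'
#' Maps an earth-frame vector into the body frame under the package's
#' conventions (`v_body = Rx(-roll) Ry(-pitch) Rz(yaw) v_earth`). Gravity is
#' `(0, 0, 1)` g in the earth frame. Used by the simulator and by round-trip
#' tests; [attitude()] is its exact inverse on noiseless data.
#'
#' @param pitch,roll,yaw Angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
body_rotation <- function(pitch, roll, yaw = 0) {
  p <- deg2rad(pitch); r <- deg2rad(roll); w <- deg2rad(yaw)
  rx <- matrix(c(1, 0, 0,
                 0, cos(-r), -sin(-r),
                 0, sin(-r), cos(-r)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(-p), 0, sin(-p),
                 0, 1, 0,
                 -sin(-p), 0, cos(-p)), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(w), -sin(w), 0,
                 sin(w), cos(w), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  rx %*% ry %*% rz
}

#' RMS rotational velocity over a window
#'
#' The gyroscope oscillates around zero with stroking, so its RMS measures
#' the average rotational energy — a per-dive proxy for stroking effort.
#' Axes are combined as the per-sample vector norm before taking the RMS
#' (`mode = "vector"`); `mode = "axis_sum"` instead sums per-axis RMS values.
#'
#' @param gyro Data frame with gyroscope columns `gx, gy, gz` (deg/s).
#' @param start,end Half-open sample-index window `[start, end)`; defaults to
#'   the whole series.
#' @param mode Axis combination rule, `"vector"` (default) or `"axis_sum"`.
#' @return RMS rotational velocity (deg/s).
#' @export
gyro_rms <- function(gyro, start = 1L, end = nrow(gyro) + 1L,
                     mode = c("vector", "axis_sum")) {
  mode <- match.arg(mode)
  check_columns(gyro, c("gx", "gy", "gz"), "gyroscope")
  if (end <= start) abort("empty window: `end` must exceed `start`.",
                          class = "sealsearch_domain_error")
  idx <- seq.int(start, end - 1L)
  gx <- gyro$gx[idx]; gy <- gyro$gy[idx]; gz <- gyro$gz[idx]
  if (mode == "vector") {
    sqrt(mean(gx^2 + gy^2 + gz^2))
  } else {
    sqrt(mean(gx^2)) + sqrt(mean(gy^2)) + sqrt(mean(gz^2))
  }
}

#' Derive all kinematic channels for a sensor series
#'
#' Convenience wrapper running [separate_gravity()], [odba()] and
#' [attitude()] and appending the derived channels to the series.
#'
#' @param series A [sensor_series()].
#' @param window_s Gravity-filter window (s).
#' @param norm_floor Static-norm floor for valid attitude (g).
#' @param flip_pitch Set `TRUE` for tags mounted backwards (flips the pitch
#'   sign so positive stays head-down).
#' @return The series with columns `sx..dz`, `odba`, `pitch`, `roll`, `yaw`,
#'   `valid` appended.
#' @export
derive_kinematics <- function(series, window_s = 2, norm_floor = 0.3,
                              flip_pitch = FALSE) {
  fs <- sampling_rate(series)
  parts <- separate_gravity(series, fs, window_s)
  att <- attitude(parts[c("sx", "sy", "sz")],
                  series[c("mx", "my", "mz")], norm_floor)
  if (flip_pitch) att$pitch <- -att$pitch
  out <- dplyr::bind_cols(as_tibble(series), parts,
                          tibble(odba = odba(parts)), att)
  structure(out, class = class(series), fs = fs,
            seal_id = attr(series, "seal_id"), t0 = attr(series, "t0"))
}
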