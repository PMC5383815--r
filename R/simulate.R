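# Synthetic-data generators with known ground truth.
#
# Two levels: simulate_dive_table() draws per-dive covariates and search
# outcomes straight from the hierarchical logistic model (for validating the
# fitter), while simulate_sensor_trip() synthesises raw 100 Hz-class sensor
# streams — square benthic dives, head-down search inversions, stroking
# oscillations — whose kinematics recover the planted attitude (for
# validating the full processing chain and the detector).

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' and acceptance suites: six seals carrying tags over square benthic dives,
#' with search probability following a logistic model with per-seal random
#' intercepts. The fixed-effect defaults are coefficients estimated for
#' wild benthic-foraging monk seals (bathymetry in m, shore distance in km,
#' dive duration in minutes, mean ODBA in g, dive ratio and bottom time as
#' proportions); the intercept is not part of that published set and is an
#' explicit, documented simulation choice.
#'
#' @param n_seals Number of seals.
#' @param n_trips_per_seal Trips per seal.
#' @param n_dives_per_trip Dives per trip.
#' @param fs Sensor sampling rate, Hz (100 for realism; 10-25 is adequate
#'   for the detector and much faster).
#' @param descent_rate,ascent_rate Vertical travel rates (m/s).
#' @param bottom_shape,bottom_mean_s Gamma parameters of bottom duration (s).
#' @param surface_mean_s Mean surface interval between dives (s).
#' @param p_search_dive Probability a simulated dive carries search events
#'   (sensor-level simulator; most dives of a benthic forager do).
#' @param events_extra_lambda Searching dives carry `1 + Poisson(lambda)`
#'   events.
#' @param event_duration_range Event duration range (s), drawn uniformly.
#' @param event_pitch_range Head-down pitch during events (deg, > 70).
#' @param descent_pitch Head-down pitch in the top few metres of descent
#'   (deg; above threshold, excluded by the depth gate).
#' @param subsurface_descent_pitch Pitch for the rest of the descent (deg;
#'   kept just below threshold — seals flatten once past the initial
#'   near-vertical drop).
#' @param descent_pitch_depth_m Depth at which descent pitch relaxes (m).
#' @param stroke_amp_gyro,stroke_freq_hz Stroking oscillation on the
#'   gyroscope (deg/s, Hz).
#' @param stroke_dyn_amp Dynamic-acceleration amplitude of stroking (g).
#' @param event_gyro_amp,event_dyn_amp,event_dyn_freq_hz Extra rotational
#'   and dynamic-acceleration energy during search events.
#' @param acc_noise_sd,mag_noise_sd,gyro_noise_sd,depth_noise_sd Per-channel
#'   sensor noise scales (g, field units, deg/s, m).
#' @param mag_field Earth magnetic field vector in the earth frame.
#' @param beta0 True model intercept (logit scale).
#' @param beta Named true fixed-effect vector (names must match the model
#'   frame columns).
#' @param sigma_alpha Between-seal random-intercept standard deviation.
#' @param bathy_range,duration_shape,duration_mean_min,odba_mean,odba_cv,
#'   ratio_shape1,ratio_shape2,bottom_shape1,bottom_shape2,shore_range
#'   Covariate distributions of the dive-table generator: bathymetry
#'   Uniform (m), duration Gamma (min), mean ODBA log-normal (g), dive ratio
#'   and bottom proportion Beta, shore distance Uniform (km).
#' @param grid_bathy_range Bathymetry range of the synthetic raster (m).
#' @param grid_n Cells per side of the synthetic raster.
#' @param grid_cellsize Raster cell size (m).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_seals = 6, n_trips_per_seal = 2, n_dives_per_trip = 20,
                       fs = 100,
                       descent_rate = 1.2, ascent_rate = 1.2,
                       bottom_shape = 4, bottom_mean_s = 150,
                       surface_mean_s = 60,
                       p_search_dive = 0.8, events_extra_lambda = 1.5,
                       event_duration_range = c(4, 12),
                       event_pitch_range = c(73, 88),
                       descent_pitch = 80, subsurface_descent_pitch = 62,
                       descent_pitch_depth_m = -2.2,
                       stroke_amp_gyro = 20, stroke_freq_hz = 1.2,
                       stroke_dyn_amp = 0.04,
                       event_gyro_amp = 80, event_dyn_amp = 0.15,
                       event_dyn_freq_hz = 3,
                       acc_noise_sd = 0.02, mag_noise_sd = 0.5,
                       gyro_noise_sd = 2, depth_noise_sd = 0.05,
                       mag_field = c(25, 0, -40),
                       beta0 = -2.5,
                       beta = c(bathymetry_m = -0.038, shore_km = 0.016,
                                duration_min = 0.66, mean_odba = 9.077,
                                dive_ratio = 2.65, bottom_prop = 1.15),
                       sigma_alpha = 0.5,
                       bathy_range = c(-100, -5),
                       duration_shape = 4, duration_mean_min = 5,
                       odba_mean = 0.15, odba_cv = 0.4,
                       ratio_shape1 = 5, ratio_shape2 = 2,
                       bottom_shape1 = 6, bottom_shape2 = 3,
                       shore_range = c(0, 20),
                       grid_bathy_range = c(-60, -8),
                       grid_n = 20, grid_cellsize = 1000) {
  cfg <- as.list(environment())
  stopifnot(cfg$fs > 0, cfg$descent_rate > 0, cfg$ascent_rate > 0,
            cfg$sigma_alpha >= 0,
            cfg$event_pitch_range[1] > 70, cfg$event_pitch_range[2] <= 90)
  structure(cfg, class = "sim_config")
}

dives_per_seal <- function(config) config$n_trips_per_seal * config$n_dives_per_trip

#' Simulate a dive table from the hierarchical logistic model
#'
#' Draws per-dive covariates from the configured distributions, per-seal
#' random intercepts `alpha_k ~ Normal(0, sigma_alpha^2)`, and search
#' outcomes `y ~ Bernoulli(plogis(beta0 + x beta + alpha_k))`. Each seal has
#' its own RNG stream derived from the master seed, so adding seals never
#' perturbs earlier seals. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Master RNG seed.
#' @return List with `dives` (tibble: ids, covariates in model units,
#'   `searching`) and `truth` (list: `beta0`, `beta`, `sigma_alpha`, `alpha`
#'   per seal, per-dive `theta`).
#' @export
simulate_dive_table <- function(config = sim_config(), seed = 1) {
  n_per_seal <- dives_per_seal(config)
  beta <- config$beta
  per_seal <- purrr::map(seq_len(config$n_seals), function(k) {
    with_seed(derive_seed(seed, 1L, k), {
      alpha_k <- rnorm(1, 0, config$sigma_alpha)
      sdlog <- sqrt(log(1 + config$odba_cv^2))
      d <- tibble(
        seal_id = sprintf("sim%02d", k),
        bathymetry_m = runif(n_per_seal, config$bathy_range[1], config$bathy_range[2]),
        duration_min = rgamma(n_per_seal, shape = config$duration_shape,
                              rate = config$duration_shape / config$duration_mean_min),
        mean_odba = rlnorm(n_per_seal, meanlog = log(config$odba_mean) - sdlog^2 / 2,
                           sdlog = sdlog),
        dive_ratio = rbeta(n_per_seal, config$ratio_shape1, config$ratio_shape2),
        bottom_prop = rbeta(n_per_seal, config$bottom_shape1, config$bottom_shape2),
        shore_km = runif(n_per_seal, config$shore_range[1], config$shore_range[2])
      )
      x <- as.matrix(d[names(beta)])
      lp <- config$beta0 + drop(x %*% beta) + alpha_k
      if (any(!is.finite(lp))) {
        abort("non-finite linear predictor; check beta/covariate configuration.",
              class = "sealsearch_config_error")
      }
      theta <- plogis(lp)
      d$searching <- rbinom(n_per_seal, 1, theta) == 1
      list(dives = d, alpha = alpha_k, theta = theta)
    })
  })
  dives <- bind_rows(purrr::map(per_seal, "dives")) %>%
    mutate(trip_id = rep(rep(seq_len(config$n_trips_per_seal),
                             each = config$n_dives_per_trip), config$n_seals),
           dive_id = sprintf("%s-d%04d", .data$seal_id,
                             rep(seq_len(n_per_seal), config$n_seals)),
           .before = 1) %>%
    dplyr::relocate("seal_id", .before = 1)
  list(
    dives = dives,
    truth = list(beta0 = config$beta0, beta = beta,
                 sigma_alpha = config$sigma_alpha,
                 alpha = setNames(purrr::map_dbl(per_seal, "alpha"),
                                  sprintf("sim%02d", seq_len(config$n_seals))),
                 theta = unlist(purrr::map(per_seal, "theta")))
  )
}

#' Synthetic environmental raster and special polygons
#'
#' A square planar raster with per-cell bathymetry drawn uniformly from
#' `grid_bathy_range`, shore distance increasing eastward from the western
#' (shoreline) edge, a categorical habitat layer and pass-through complexity
#' layers. A rectangular "Penguin Bank" polygon covers a block of cells
#' whose habitat is forced to `"Unknown"` (a deep bank unmapped by
#' shallow-water habitat surveys).
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return List `grid` (an [env_grid()]) and `polygons` (named list).
#' @export
sim_environment <- function(config = sim_config(), seed = 1) {
  with_seed(derive_seed(seed, 2L), {
    n <- config$grid_n
    cs <- config$grid_cellsize
    bathy <- matrix(runif(n * n, config$grid_bathy_range[1],
                          config$grid_bathy_range[2]), n, n)
    centers_x <- (seq_len(n) - 0.5) * cs
    shore <- matrix(rep(centers_x / 1000, each = n), n, n)   # km from west edge
    classes <- c("pavement", "sand", "aggregate reef", "rock", "Unknown")
    habitat <- matrix(sample(classes, n * n, replace = TRUE,
                             prob = c(0.3, 0.25, 0.2, 0.15, 0.1)), n, n)
    # a deep bank in the eastern half: cells unmapped by the habitat survey
    bank_cols <- max(1, floor(0.6 * n)):max(1, floor(0.8 * n))
    bank_rows <- max(1, floor(0.3 * n)):max(1, floor(0.5 * n))
    habitat[bank_rows, bank_cols] <- "Unknown"
    # polygon in map coordinates (row 1 = north)
    x_lo <- (min(bank_cols) - 1) * cs; x_hi <- max(bank_cols) * cs
    y_hi <- (n - min(bank_rows) + 1) * cs; y_lo <- (n - max(bank_rows)) * cs
    polygons <- list("Penguin Bank" = list(x = c(x_lo, x_hi, x_hi, x_lo, x_lo),
                                           y = c(y_lo, y_lo, y_hi, y_hi, y_lo)))
    grid <- env_grid(list(bathymetry = bathy, shore_distance = shore,
                          habitat = habitat,
                          slope = matrix(runif(n * n, 0, 30), n, n),
                          ruggedness = matrix(runif(n * n), n, n),
                          rugosity = matrix(1 + runif(n * n), n, n)),
                     x0 = 0, y0 = 0, cellsize = cs)
    list(grid = grid, polygons = polygons)
  })
}

# Planted per-dive schedule for the sensor simulator: phase boundaries,
# event placement and attitude plan, all in seconds relative to dive start.
plan_dive <- function(config, bottom_depth) {
  t_desc <- abs(bottom_depth) / config$descent_rate
  t_bottom <- rgamma(1, config$bottom_shape,
                     rate = config$bottom_shape / config$bottom_mean_s)
  t_bottom <- max(t_bottom, 30)
  t_asc <- abs(bottom_depth) / config$ascent_rate
  searching <- runif(1) < config$p_search_dive
  events <- tibble(start = numeric(0), end = numeric(0), pitch = numeric(0))
  if (searching) {
    n_ev <- 1 + stats::rpois(1, config$events_extra_lambda)
    # place non-overlapping events inside the bottom phase, 2 s margins
    slots <- seq(2, t_bottom - 2 - config$event_duration_range[2],
                 length.out = max(n_ev, 1) + 1)
    n_ev <- min(n_ev, length(slots) - 1)
    if (n_ev >= 1) {
      starts <- slots[seq_len(n_ev)] +
        runif(n_ev, 0, pmax(0, diff(slots)[1] - config$event_duration_range[2]))
      durs <- runif(n_ev, config$event_duration_range[1], config$event_duration_range[2])
      events <- tibble(start = t_desc + starts, end = t_desc + starts + durs,
                       pitch = runif(n_ev, config$event_pitch_range[1],
                                     config$event_pitch_range[2]))
    }
  }
  list(t_desc = t_desc, t_bottom = t_bottom, t_asc = t_asc,
       duration = t_desc + t_bottom + t_asc,
       searching = nrow(events) > 0, events = events)
}

#' Simulate one foraging trip of raw sensor data
#'
#' Generates a square-benthic-dive depth profile over a synthetic
#' environmental raster, plants head-down search events (pitch above 70 deg,
#' always below -3 m) on searching dives, and renders fully consistent
#' accelerometer, magnetometer and gyroscope channels: gravity and the earth
#' field rotated by the planted attitude, stroking oscillations, extra
#' dynamic bursts during events, and per-channel Gaussian noise. The
#' kinematics module recovers the planted attitude from these channels.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @param seal Seal index (its RNG stream) and id suffix.
#' @param trip Trip index.
#' @param env Optional result of [sim_environment()]; generated from
#'   `config`/`seed` when omitted.
#' @return List: `sensors` (a [sensor_series()]), `gps` (track tibble),
#'   `truth` (list: per-dive tibble `dives`, per-event tibble `events`,
#'   per-sample planted `attitude`), `env`.
#' @export
simulate_sensor_trip <- function(config = sim_config(), seed = 1, seal = 1,
                                 trip = 1, env = NULL) {
  if (max(config$grid_bathy_range) > -3 && config$p_search_dive > 0) {
    abort("bottom shallower than -3 m with search events requested: events would be undetectable by design.",
          class = "sealsearch_config_error")
  }
  if (is.null(env)) env <- sim_environment(config, seed)
  grid <- env$grid
  fs <- config$fs
  with_seed(derive_seed(seed, 3L, seal, trip), {
    n_dives <- config$n_dives_per_trip
    extent <- config$grid_n * config$grid_cellsize
    # slow random walk across the raster interior
    pos <- matrix(NA_real_, n_dives, 2)
    pos[1, ] <- runif(2, 0.2 * extent, 0.8 * extent)
    if (n_dives > 1) {
      for (i in 2:n_dives) {
        step <- rnorm(2, 0, 150)
        pos[i, ] <- pmin(pmax(pos[i - 1, ] + step, 0.05 * extent), 0.95 * extent)
      }
    }
    bottom <- grid_lookup(grid, pos[, 1], pos[, 2], "bathymetry")

    t_cursor <- 0
    dive_rows <- list(); event_rows <- list(); chunks <- list()
    for (i in seq_len(n_dives)) {
      plan <- plan_dive(config, bottom[i])
      surf_n <- max(2L, round(stats::rexp(1, 1 / config$surface_mean_s) * fs))
      desc_n <- max(2L, round(plan$t_desc * fs))
      bot_n <- max(2L, round(plan$t_bottom * fs))
      asc_n <- max(2L, round(plan$t_asc * fs))
      depth <- c(rep(0, surf_n),
                 seq(0, bottom[i], length.out = desc_n),
                 rep(bottom[i], bot_n),
                 seq(bottom[i], 0, length.out = asc_n))
      n_tot <- length(depth)
      rel_t <- (seq_len(n_tot) - 1) / fs
      dive_start_rel <- surf_n / fs
      pitch <- rep(0, n_tot)
      desc_idx <- surf_n + seq_len(desc_n)
      pitch[desc_idx] <- ifelse(depth[desc_idx] > config$descent_pitch_depth_m,
                                config$descent_pitch,
                                config$subsurface_descent_pitch)
      asc_idx <- surf_n + desc_n + bot_n + seq_len(asc_n)
      pitch[asc_idx] <- -config$descent_pitch
      in_event <- rep(FALSE, n_tot)
      if (nrow(plan$events) > 0) {
        for (e in seq_len(nrow(plan$events))) {
          ev <- plan$events[e, ]
          sel <- rel_t >= dive_start_rel + ev$start & rel_t <= dive_start_rel + ev$end
          pitch[sel] <- ev$pitch
          in_event <- in_event | sel
          event_rows[[length(event_rows) + 1]] <- tibble(
            dive = i,
            start_s = t_cursor + dive_start_rel + ev$start,
            end_s = t_cursor + dive_start_rel + ev$end,
            pitch = ev$pitch)
        }
      }
      submerged <- depth < -0.01
      chunks[[i]] <- tibble(time = t_cursor + rel_t, depth = depth,
                            pitch = pitch, in_event = in_event,
                            stroking = submerged & !in_event)
      dive_rows[[i]] <- tibble(
        dive = i, x = pos[i, 1], y = pos[i, 2],
        start_s = t_cursor + dive_start_rel,
        end_s = t_cursor + (surf_n + desc_n + bot_n + asc_n - 1) / fs,
        bottom_depth = bottom[i],
        searching = plan$searching, n_events = nrow(plan$events))
      t_cursor <- t_cursor + n_tot / fs
    }
    tr <- bind_rows(chunks)
    n <- nrow(tr)
    dives <- bind_rows(dive_rows)

    yaw <- rep(runif(1, -180, 180), n)  # heading held within the trip
    roll <- rep(0, n)
    # render channels sample-by-sample from the planted attitude
    p <- deg2rad(tr$pitch); r <- deg2rad(roll); w <- deg2rad(yaw)
    g_body <- cbind(-sin(p), sin(r) * cos(p), cos(r) * cos(p))
    mf <- config$mag_field
    # m_body = Rx(-r) Ry(-p) Rz(w) m_earth, with r = 0
    mex <- cos(w) * mf[1] - sin(w) * mf[2]
    mey <- sin(w) * mf[1] + cos(w) * mf[2]
    mez <- mf[3]
    m_body <- cbind(cos(p) * mex - sin(p) * mez, mey,
                    sin(p) * mex + cos(p) * mez)
    phase <- 2 * pi * config$stroke_freq_hz * tr$time
    ev_phase <- 2 * pi * config$event_dyn_freq_hz * tr$time
    stroke <- config$stroke_amp_gyro * sin(phase) * tr$stroking
    gyro_ev <- config$event_gyro_amp * sin(ev_phase) * tr$in_event
    dyn <- config$stroke_dyn_amp * sin(phase) * tr$stroking +
      config$event_dyn_amp * sin(ev_phase) * tr$in_event
    sensors <- tibble(
      time = tr$time,
      ax = g_body[, 1] + dyn * 0.4 + rnorm(n, 0, config$acc_noise_sd),
      ay = g_body[, 2] + dyn + rnorm(n, 0, config$acc_noise_sd),
      az = g_body[, 3] + dyn * 0.6 + rnorm(n, 0, config$acc_noise_sd),
      mx = m_body[, 1] + rnorm(n, 0, config$mag_noise_sd),
      my = m_body[, 2] + rnorm(n, 0, config$mag_noise_sd),
      mz = m_body[, 3] + rnorm(n, 0, config$mag_noise_sd),
      gx = 0.3 * stroke + gyro_ev * 0.5 + rnorm(n, 0, config$gyro_noise_sd),
      gy = stroke + gyro_ev + rnorm(n, 0, config$gyro_noise_sd),
      gz = 0.2 * stroke + gyro_ev * 0.3 + rnorm(n, 0, config$gyro_noise_sd),
      depth = pmin(tr$depth + rnorm(n, 0, config$depth_noise_sd), 0)
    )
    seal_id <- sprintf("sim%02d", seal)
    series <- sensor_series(sensors, fs = fs, seal_id = seal_id)
    gps <- tibble(time = c(0, dives$start_s, t_cursor),
                  x = c(pos[1, 1], pos[, 1], pos[n_dives, 1]),
                  y = c(pos[1, 2], pos[, 2], pos[n_dives, 2])) %>%
      dplyr::distinct(.data$time, .keep_all = TRUE) %>%
      arrange(.data$time)
    events <- if (length(event_rows)) bind_rows(event_rows) else
      tibble(dive = integer(0), start_s = numeric(0), end_s = numeric(0),
             pitch = numeric(0))
    list(sensors = series, gps = gps,
         truth = list(dives = dives, events = events,
                      attitude = tibble(time = tr$time, pitch = tr$pitch,
                                        roll = roll, yaw = yaw,
                                        in_event = tr$in_event)),
         env = env)
  })
}

#' Simulate a multi-seal, multi-trip deployment of raw sensor data
#'
#' @inheritParams simulate_sensor_trip
#' @return List with one element per (seal, trip) as returned by
#'   [simulate_sensor_trip()], plus the shared `env`.
#' @export
simulate_deployment <- function(config = sim_config(), seed = 1) {
  env <- sim_environment(config, seed)
  trips <- list()
  for (k in seq_len(config$n_seals)) {
    for (tr in seq_len(config$n_trips_per_seal)) {
      trips[[length(trips) + 1]] <-
        simulate_sensor_trip(config, seed, seal = k, trip = tr, env = env)
    }
  }
  list(trips = trips, env = env)
}
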