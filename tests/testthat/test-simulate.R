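test_that("dive-table simulation is deterministic given the seed", {
  cfg <- sim_config(n_seals = 3, n_trips_per_seal = 1, n_dives_per_trip = 30)
  a <- simulate_dive_table(cfg, seed = 9)
  b <- simulate_dive_table(cfg, seed = 9)
  expect_identical(a$dives, b$dives)
  expect_identical(a$truth$alpha, b$truth$alpha)
  c <- simulate_dive_table(cfg, seed = 10)
  expect_false(identical(a$dives$searching, c$dives$searching))
})

test_that("per-seal RNG streams: adding seals never perturbs earlier seals", {
  small <- sim_config(n_seals = 2, n_trips_per_seal = 1, n_dives_per_trip = 40)
  big <- sim_config(n_seals = 4, n_trips_per_seal = 1, n_dives_per_trip = 40)
  a <- simulate_dive_table(small, seed = 9)$dives
  b <- simulate_dive_table(big, seed = 9)$dives
  expect_identical(a, b[b$seal_id %in% c("sim01", "sim02"), ])
})

test_that("a null model yields a half-and-half outcome split", {
  cfg <- sim_config(n_seals = 5, n_trips_per_seal = 2, n_dives_per_trip = 1000,
                    beta0 = 0, sigma_alpha = 0)
  cfg$beta <- cfg$beta * 0
  sim <- simulate_dive_table(cfg, seed = 17)
  expect_equal(nrow(sim$dives), 10000)
  expect_lt(abs(mean(sim$dives$searching) - 0.5), 0.015)
})

test_that("the empirical search rate matches a Monte-Carlo oracle of the model", {
  cfg <- sim_config(n_seals = 6, n_trips_per_seal = 1, n_dives_per_trip = 500)
  sim <- simulate_dive_table(cfg, seed = 23)
  # brute-force oracle: 1e6 fresh draws of logit^-1(beta0 + x beta)
  withr::local_seed(24)
  n <- 1e6
  sdlog <- sqrt(log(1 + cfg$odba_cv^2))
  x <- cbind(bathymetry_m = runif(n, -100, -5),
             shore_km = runif(n, 0, 20),
             duration_min = rgamma(n, 4, rate = 4 / 5),
             mean_odba = rlnorm(n, log(0.15) - sdlog^2 / 2, sdlog),
             dive_ratio = rbeta(n, 5, 2),
             bottom_prop = rbeta(n, 6, 3))
  oracle <- mean(plogis(cfg$beta0 + drop(x[, names(cfg$beta)] %*% cfg$beta)))
  expect_lt(abs(mean(sim$dives$searching) - oracle), 0.05)
})

test_that("a misconfigured linear predictor raises a config error", {
  cfg <- sim_config(n_seals = 2, n_trips_per_seal = 1, n_dives_per_trip = 5)
  cfg$beta["mean_odba"] <- Inf
  expect_error(simulate_dive_table(cfg, seed = 1),
               class = "sealsearch_config_error")
})

test_that("planted search events lie within dives and below the depth gate", {
  truth <- fx_trip$truth
  expect_gt(nrow(truth$events), 0)
  for (i in seq_len(nrow(truth$events))) {
    ev <- truth$events[i, ]
    dive <- truth$dives[ev$dive, ]
    expect_gte(ev$start_s, dive$start_s)
    expect_lte(ev$end_s, dive$end_s)
    expect_gt(ev$pitch, 70)
  }
  # every event sample is deeper than -3 m
  sens <- fx_trip$sensors
  for (i in seq_len(nrow(truth$events))) {
    sel <- sens$time >= truth$events$start_s[i] &
      sens$time <= truth$events$end_s[i]
    expect_true(all(sens$depth[sel] <= -3))
  }
  expect_true(all(sens$depth <= 0))
  expect_equal(truth$dives$searching, truth$dives$n_events > 0)
})

test_that("shallow bathymetry with events requested is rejected", {
  cfg <- sim_config(grid_bathy_range = c(-2.5, -1))
  expect_error(simulate_sensor_trip(cfg, seed = 1),
               class = "sealsearch_config_error")
})

test_that("seeded sensor simulation reproduces byte-identical CSV output", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_seals = 1, n_trips_per_seal = 1, n_dives_per_trip = 2,
                    fs = 10)
  p1 <- file.path(dir, "a.csv"); p2 <- file.path(dir, "b.csv")
  write_sensor_csv(simulate_sensor_trip(cfg, seed = 3)$sensors, p1)
  write_sensor_csv(simulate_sensor_trip(cfg, seed = 3)$sensors, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("noiseless sensor channels recover the planted pitch within a degree", {
  trip <- simulate_sensor_trip(noiseless_cfg, seed = 7)
  kin <- derive_kinematics(trip$sensors)
  truth <- trip$truth$attitude
  # exclude the gravity-filter edge around each planted discontinuity
  jumps <- which(abs(diff(truth$pitch)) > 1e-9)
  fs <- sampling_rate(trip$sensors)
  margin <- ceiling(1.5 * fs)
  near <- unique(unlist(lapply(jumps, function(j) {
    max(1, j - margin):min(nrow(kin), j + margin)
  })))
  keep <- setdiff(seq_len(nrow(kin)), near)
  expect_lt(max(abs(kin$pitch[keep] - truth$pitch[keep]), na.rm = TRUE), 1)
})

test_that("outcomes are exchangeable across seals when sigma_alpha is zero", {
  cfg <- sim_config(n_seals = 6, n_trips_per_seal = 1, n_dives_per_trip = 400,
                    sigma_alpha = 0)
  sim <- simulate_dive_table(cfg, seed = 31)
  expect_true(all(sim$truth$alpha == 0))
  rates <- tapply(sim$dives$searching, sim$dives$seal_id, mean)
  expect_lt(diff(range(rates)), 0.12)
})
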