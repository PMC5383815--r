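# Shared fixtures, built once per test run. Sensor simulations run at 10 Hz:
# ample for the 2 s gravity filter and the event durations in play.

fast_cfg <- sim_config(n_seals = 2, n_trips_per_seal = 1, n_dives_per_trip = 5,
                       fs = 10)

noiseless_cfg <- sim_config(
  n_seals = 1, n_trips_per_seal = 1, n_dives_per_trip = 3, fs = 10,
  acc_noise_sd = 0, mag_noise_sd = 0, gyro_noise_sd = 0, depth_noise_sd = 0,
  stroke_dyn_amp = 0, event_dyn_amp = 0)

# one default-noise trip reused across dive/search/covariate tests
fx_trip <- simulate_sensor_trip(fast_cfg, seed = 11)
fx_kin <- derive_kinematics(fx_trip$sensors)

# a small sensor tibble builder for hand-constructed cases
make_sensor_tbl <- function(n, fs = 10, depth = 0, ax = 0, ay = 0, az = 1,
                            mx = 1, my = 0, mz = 0, gx = 0, gy = 0, gz = 0) {
  tibble::tibble(time = (seq_len(n) - 1) / fs,
                 ax = rep_len(ax, n), ay = rep_len(ay, n), az = rep_len(az, n),
                 mx = rep_len(mx, n), my = rep_len(my, n), mz = rep_len(mz, n),
                 gx = rep_len(gx, n), gy = rep_len(gy, n), gz = rep_len(gz, n),
                 depth = rep_len(depth, n))
}

# smallest-angle absolute difference in degrees
ang_diff <- function(a, b) abs((a - b + 180) %% 360 - 180)
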