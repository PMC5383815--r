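test_that("no dives are found in a shallow record", {
  expect_equal(nrow(detect_dives(rep(-0.5, 500), fs = 10)), 0)
  expect_equal(nrow(detect_dives(numeric(0), fs = 10)), 0)
})

test_that("a square excursion is one dive with the constructed depth and duration", {
  fs <- 10
  depth <- c(rep(0, 50), rep(-20, 300 * fs), rep(0, 50))
  d <- detect_dives(depth, fs)
  expect_equal(nrow(d), 1)
  seg <- depth[d$start[1]:d$end[1]]
  expect_equal(min(seg), -20)
  expect_lt(abs((d$end[1] - d$start[1] + 1) / fs - 300), 2 / fs + 1e-9)
})

test_that("segmentation agrees with a naive per-sample oracle on random profiles", {
  # oracle: independently walk the thresholded mask sample by sample,
  # extend to surface crossings, drop short dives
  oracle <- function(depth, fs, thr = -1.5, min_s = 8, surf = -0.25) {
    n <- length(depth)
    seen <- rep(FALSE, n)
    out <- list()
    for (i in seq_len(n)) {
      if (depth[i] < thr && !seen[i]) {
        a <- i; while (a > 1 && depth[a - 1] < surf) a <- a - 1
        b <- i; while (b < n && depth[b + 1] < surf) b <- b + 1
        seen[a:b] <- TRUE
        if ((b - a + 1) / fs >= min_s) out[[length(out) + 1]] <- c(a, b)
      }
    }
    if (length(out) == 0) return(tibble::tibble(start = integer(0), end = integer(0)))
    m <- do.call(rbind, out)
    tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  }
  withr::local_seed(21)
  fs <- 5
  for (rep_i in 1:100) {
    depth <- pmin(0, -3 * abs(cumsum(rnorm(400))) / 10 +
                    rnorm(400, 0, 0.3) + 1.2)
    got <- detect_dives(depth, fs)
    want <- oracle(depth, fs)
    expect_equal(as.data.frame(got), as.data.frame(want))
    # partition property: every sample deeper than threshold in exactly one dive
    deep <- which(depth < -1.5)
    if (nrow(got) > 0) {
      member <- rowSums(outer(deep, got$start, ">=") &
                          outer(deep, got$end, "<="))
      short <- deep[member == 0]
      # samples not covered can only come from dives dropped as too short
      expect_true(all(member <= 1))
      expect_true(all(vapply(short, function(i) {
        any(want$start <= i & want$end >= i) == FALSE
      }, logical(1))))
    }
  }
})

test_that("bottom time matches analytic dive shapes", {
  fs <- 10
  # ideal square dive: instant descent/ascent
  sq <- c(-0.1, rep(-30, 200), -0.1)
  bt <- bottom_time(sq, fs)
  expect_gt(bt$bottom_pct, 98)

  # symmetric V dive: the fraction deeper than 0.8 * max is 0.2
  v <- -30 * c(seq(0, 1, length.out = 500), seq(1, 0, length.out = 500)[-1])
  bt <- bottom_time(v, fs)
  expect_equal(bt$bottom_pct, 20, tolerance = 100 / length(v))

  # trapezoid: 1 m/s ramps to -30 m, 240 s bottom; time deeper than -24 m
  # is 240 s plus 6 s on each ramp
  ramp <- seq(0, -30, by = -1 / fs)
  tz <- c(ramp, rep(-30, 240 * fs), rev(ramp))
  bt <- bottom_time(tz, fs)
  analytic <- 240 + 2 * 6
  expect_equal(bt$bottom_time_s, analytic, tolerance = 3 / fs / analytic)

  expect_error(bottom_time(numeric(0), fs), class = "sealsearch_domain_error")
})

test_that("dive summaries recover the simulator's planted values", {
  trip <- simulate_sensor_trip(noiseless_cfg, seed = 13)
  kin <- derive_kinematics(trip$sensors)
  res <- summarize_dives(kin)
  truth <- trip$truth$dives
  expect_equal(nrow(res$dives), nrow(truth))
  expect_equal(res$dives$start_s, truth$start_s, tolerance = 0.2)
  expect_equal(res$dives$max_depth, truth$bottom_depth, tolerance = 0.01)
  expect_equal(res$dives$searching, truth$searching)
  expect_equal(res$dives$n_search_events, truth$n_events)
  # planted search time within one smoothing window per event
  planted <- vapply(seq_len(nrow(truth)), function(i) {
    ev <- trip$truth$events[trip$truth$events$dive == i, ]
    sum(ev$end_s - ev$start_s)
  }, numeric(1))
  expect_equal(res$dives$search_time_s, planted,
               tolerance = 0.25)
})

test_that("mean odba is zero for a dive with no dynamic acceleration", {
  trip <- simulate_sensor_trip(noiseless_cfg, seed = 14)
  kin <- derive_kinematics(trip$sensors)
  res <- summarize_dives(kin)
  # noiseless config has no stroking or event dynamics: odba ~ 0 except at
  # attitude transitions smeared by the gravity filter
  expect_lt(min(res$dives$mean_odba), 0.05)
  expect_error(summarize_dive(kin, 10, nrow(kin) + 5),
               class = "sealsearch_index_error")
})

test_that("deployment summaries equal direct recomputation", {
  res <- summarize_dives(fx_kin)
  s <- summarize_deployment(res$dives)
  expect_equal(s$n_dives, nrow(res$dives))
  expect_equal(s$depth_mean, mean(abs(res$dives$max_depth)))
  expect_equal(s$duration_min_mean, mean(res$dives$duration_s) / 60)
  expect_equal(s$bottom_pct_mean, mean(res$dives$bottom_pct))
  expect_equal(s$p_searching, mean(res$dives$searching))

  one <- summarize_deployment(res$dives[1, ])
  expect_equal(one$n_dives, 1)
  expect_equal(one$depth_sd, 0)

  two <- summarize_deployment(res$dives[c(1, 1), ])
  expect_equal(two$depth_sd, 0)
  expect_equal(two$depth_mean, abs(res$dives$max_depth[1]))
})

test_that("trips split on long surface gaps", {
  dives <- tibble::tibble(start_s = c(0, 500, 4000), end_s = c(400, 900, 4400))
  expect_equal(assign_trips(dives, gap_min = 30), c(1L, 1L, 2L))
})
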