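make_grid <- function(n = 5, cs = 1000) {
  env_grid(list(bathymetry = matrix(-(1:(n * n)), n, n),
                shore_distance = matrix(runif(n * n, 0, 20), n, n),
                habitat = matrix("sand", n, n)),
           x0 = 0, y0 = 0, cellsize = cs)
}

test_that("grid lookup returns the cell containing the point, half-open at edges", {
  g <- make_grid()
  # cell centre of column 1, bottom row (row index n = 5 at the south edge)
  expect_equal(grid_lookup(g, 500, 500, "bathymetry"), g$layers$bathymetry[5, 1])
  # a point exactly on the shared edge belongs to the next (right/up) cell
  expect_equal(grid_lookup(g, 1000, 500, "bathymetry"), g$layers$bathymetry[5, 2])
  expect_equal(grid_lookup(g, 500, 1000, "bathymetry"), g$layers$bathymetry[4, 1])
  expect_error(grid_lookup(g, -1, 500, "bathymetry"),
               class = "sealsearch_bounds_error")
  expect_error(grid_lookup(g, 5000, 500, "bathymetry"),
               class = "sealsearch_bounds_error")
})

test_that("grid lookup agrees with brute-force nearest-centre search on 1000 points", {
  withr::local_seed(41)
  g <- make_grid(8, 500)
  centres <- expand.grid(col = 1:8, row = 1:8)
  centres$x <- (centres$col - 0.5) * 500
  centres$y <- (8 - centres$row + 0.5) * 500
  centres$val <- g$layers$bathymetry[cbind(centres$row, centres$col)]
  x <- runif(1000, 0, 4000); y <- runif(1000, 0, 4000)
  got <- grid_lookup(g, x, y, "bathymetry")
  want <- vapply(seq_along(x), function(i) {
    centres$val[which.min((centres$x - x[i])^2 + (centres$y - y[i])^2)]
  }, numeric(1))
  expect_equal(got, want)
  # idempotent, purely positional
  expect_equal(grid_lookup(g, x, y, "bathymetry"), got)
})

test_that("dive ratio handles benthic, exact-bottom and over-deep dives", {
  expect_equal(dive_ratio(-20, -25)$dive_ratio, 0.8)
  expect_equal(dive_ratio(-25, -25)$dive_ratio, 1.0)
  over <- dive_ratio(-30, -25)
  expect_equal(over$dive_ratio, 1.2)
  expect_true(over$ratio_flag)
  expect_false(dive_ratio(-20, -25)$ratio_flag)
  expect_error(dive_ratio(-20, 0), class = "sealsearch_domain_error")
})

test_that("habitat recode applies to Unknown cells inside the polygon only", {
  n <- 4
  hab <- matrix("Unknown", n, n); hab[1, 1] <- "sand"
  g <- env_grid(list(bathymetry = matrix(-50, n, n), habitat = hab),
                cellsize = 1000)
  bank <- list(x = c(0, 2000, 2000, 0, 0), y = c(2000, 2000, 4000, 4000, 2000))
  polys <- list("Penguin Bank" = bank)
  # Unknown inside the polygon -> recoded
  expect_equal(assign_habitat(g, 500, 2500, polys), "Penguin Bank")
  # Unknown outside any polygon -> stays Unknown
  expect_equal(assign_habitat(g, 3500, 500, polys), "Unknown")
  # surveyed habitat inside the polygon -> never overwritten (cell [1,1])
  expect_equal(assign_habitat(g, 500, 3500, polys), "sand")
})

test_that("covariate join interpolates the track at the dive start", {
  g <- make_grid()
  track <- tibble::tibble(time = c(0, 100), x = c(500, 1500), y = c(500, 500))
  dives <- tibble::tibble(dive_id = c("d1", "d2"), start_s = c(0, 50),
                          max_depth = c(-4, -4))
  out <- join_covariates(dives, track, g)
  # dive at a fix: that fix's cell
  expect_equal(out$bathymetry_m[1], g$layers$bathymetry[5, 1])
  # dive midway between fixes in adjacent cells: the midpoint's cell
  expect_equal(out$x[2], 1000)
  expect_equal(out$bathymetry_m[2], g$layers$bathymetry[5, 2])

  late <- tibble::tibble(dive_id = "d9", start_s = 500, max_depth = -4)
  expect_error(join_covariates(late, track, g), class = "sealsearch_join_error")
  expect_error(join_covariates(late, track, g), "d9")
})

test_that("joined bathymetry reproduces the simulator's local bottom depth", {
  res <- summarize_dives(fx_kin)
  joined <- join_covariates(res$dives, fx_trip$gps, fx_trip$env$grid,
                            fx_trip$env$polygons)
  truth <- fx_trip$truth$dives
  match_frac <- mean(abs(joined$bathymetry_m - truth$bottom_depth) < 1e-9)
  expect_gte(match_frac, 0.99)
  # benthic dives: ratio in [0, 1] up to depth-sensor noise
  expect_true(all(joined$dive_ratio <= 1.05))
})

test_that("ASCII grids round-trip numeric and categorical layers", {
  dir <- withr::local_tempdir()
  m <- matrix(round(runif(12, -60, -5), 3), 3, 4)
  p <- file.path(dir, "bathymetry.asc")
  write_ascii_grid(m, p, x0 = 100, y0 = 200, cellsize = 250)
  back <- read_ascii_grid(p)
  expect_equal(back$matrix, m, tolerance = 1e-9)
  expect_equal(c(back$x0, back$y0, back$cellsize), c(100, 200, 250))

  h <- matrix(c("sand", "rock", "Unknown", "pavement", "sand", "rock"), 2, 3)
  ph <- file.path(dir, "habitat.asc")
  write_ascii_grid(h, ph, cellsize = 1000)
  expect_equal(read_ascii_grid(ph)$matrix, h)
})
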