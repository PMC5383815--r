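# Environmental covariates: regular planar raster stack (1 km cells by
# default) carrying bathymetry, shore distance, habitat class and optional
# sea-floor complexity layers, plus the per-dive join.

#' Construct an environmental grid
#'
#' A regular planar raster stack. Layers are matrices indexed `[row, col]`
#' with row 1 at the NORTH (top) edge, matching the ESRI ASCII grid layout.
#' Cell membership is half-open: a point `(x, y)` belongs to cell
#' `i = floor((x - x0) / cellsize)` (and likewise in y), so a point on a
#' shared edge is assigned to the cell on its right/top side's origin.
#'
#' @param layers Named list of equally sized matrices; numeric layers plus an
#'   optional character `habitat` layer. `bathymetry` must be <= 0.
#' @param x0,y0 Coordinates of the lower-left corner (m).
#' @param cellsize Cell edge length (m, default 1000).
#' @return An `env_grid` object.
#' @export
env_grid <- function(layers, x0 = 0, y0 = 0, cellsize = 1000) {
  stopifnot(length(layers) > 0, !is.null(names(layers)))
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1) abort("all grid layers must share the same shape.")
  if ("bathymetry" %in% names(layers) &&
      any(layers$bathymetry > 0, na.rm = TRUE)) {
    abort("bathymetry layer must be <= 0 (negative metres below the surface).")
  }
  structure(list(layers = layers, x0 = x0, y0 = y0, cellsize = cellsize,
                 nrows = dims[[1]][1], ncols = dims[[1]][2]),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %d x %d cells of %g m; layers: %s\n",
              x$nrows, x$ncols, x$cellsize,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

grid_cell_index <- function(grid, x, y) {
  ci <- floor((x - grid$x0) / grid$cellsize)   # 0-based column from west
  cj <- floor((y - grid$y0) / grid$cellsize)   # 0-based row from south
  oob <- ci < 0 | ci >= grid$ncols | cj < 0 | cj >= grid$nrows |
    !is.finite(x) | !is.finite(y)
  list(row = grid$nrows - cj, col = ci + 1L, oob = oob)  # row 1 = north
}

#' Look up a grid layer at point locations
#'
#' Returns the value of the cell containing each point (purely positional;
#' no interpolation between cells — covariates are read from the cell the
#' point falls in, as for values extracted at the centre of a 1 km grid).
#'
#' @param grid An [env_grid()].
#' @param x,y Point coordinates (m), vectorised.
#' @param layer Layer name.
#' @return Vector of cell values.
#' @export
grid_lookup <- function(grid, x, y, layer) {
  if (!layer %in% names(grid$layers)) {
    abort(sprintf("no layer named '%s' in grid.", layer))
  }
  idx <- grid_cell_index(grid, x, y)
  if (any(idx$oob)) {
    abort(sprintf("%d point(s) outside the grid extent (first: x=%.1f, y=%.1f).",
                  sum(idx$oob), x[which(idx$oob)[1]], y[which(idx$oob)[1]]),
          class = "sealsearch_bounds_error")
  }
  grid$layers[[layer]][cbind(idx$row, idx$col)]
}

#' Dive ratio: maximum dive depth over local bathymetry
#'
#' Both quantities are negative metres, so the ratio is >= 0 and is ~1 for
#' benthic (bottom-reaching) dives. Ratios above 1 mean the recorded dive
#' went deeper than the charted bottom — possible with raster error — and
#' are allowed but flagged.
#'
#' @param max_depth Maximum dive depth (m, negative), vectorised.
#' @param bathymetry Bathymetry at the dive location (m, strictly negative).
#' @return Tibble `dive_ratio`, `ratio_flag` (`TRUE` when ratio > 1).
#' @export
dive_ratio <- function(max_depth, bathymetry) {
  if (any(bathymetry == 0, na.rm = TRUE)) {
    abort("bathymetry of 0 m: dive ratio undefined at the shoreline.",
          class = "sealsearch_domain_error")
  }
  r <- max_depth / bathymetry
  tibble(dive_ratio = r, ratio_flag = r > 1)
}

# Ray-casting point-in-polygon; ring is a closed or open coordinate ring.
point_in_polygon <- function(x, y, ring_x, ring_y) {
  n <- length(ring_x)
  if (ring_x[1] == ring_x[n] && ring_y[1] == ring_y[n]) n <- n - 1
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring_x[i]; yi <- ring_y[i]; xj <- ring_x[j]; yj <- ring_y[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Assign habitat class at point locations
#'
#' Habitat is read from the grid's `habitat` layer. Cells mapped as
#' `"Unknown"` (typically deep water beyond the reach of shallow-water
#' habitat surveys) that fall inside a named special polygon are recoded to
#' that polygon's name — e.g. a submarine bank that the habitat survey left
#' unmapped. The recode applies to `"Unknown"` cells only; surveyed classes
#' are never overwritten.
#'
#' @param grid An [env_grid()] with a `habitat` layer.
#' @param x,y Point coordinates (m), vectorised.
#' @param special_polygons Named list of polygons, each a data frame/list
#'   with `x` and `y` ring coordinates (closed or open ring).
#' @return Character vector of habitat classes.
#' @export
assign_habitat <- function(grid, x, y, special_polygons = list()) {
  hab <- grid_lookup(grid, x, y, "habitat")
  for (nm in names(special_polygons)) {
    poly <- special_polygons[[nm]]
    in_poly <- point_in_polygon(x, y, poly$x, poly$y)
    hab[hab == "Unknown" & in_poly] <- nm
  }
  hab
}

#' Join per-dive environmental covariates
#'
#' The dive location is the GPS track linearly interpolated at the dive
#' START time (habitat and all other covariates are anchored at the same
#' point for consistency). Bathymetry, shore distance, habitat, optional
#' complexity layers and the dive ratio are attached to each dive row.
#'
#' @param dives Dive tibble with `dive_id`, `start_s`, `max_depth`.
#' @param track GPS track tibble `time, x, y` (planar m).
#' @param grid An [env_grid()] with layers `bathymetry`, `shore_distance`
#'   (km) and optionally `habitat`, `slope`, `ruggedness`, `rugosity`.
#' @param special_polygons Passed to [assign_habitat()].
#' @return `dives` with covariate columns `x, y, bathymetry_m, shore_km,
#'   habitat, dive_ratio, ratio_flag` (+ any complexity layers) appended.
#' @export
join_covariates <- function(dives, track, grid, special_polygons = list()) {
  check_columns(dives, c("dive_id", "start_s", "max_depth"), "dive table")
  check_columns(track, c("time", "x", "y"), "GPS track")
  outside <- dives$start_s < min(track$time) | dives$start_s > max(track$time)
  if (any(outside)) {
    abort(sprintf("dive start outside the GPS track span for: %s",
                  paste(dives$dive_id[outside], collapse = ", ")),
          class = "sealsearch_join_error")
  }
  x <- approx(track$time, track$x, xout = dives$start_s, rule = 1)$y
  y <- approx(track$time, track$y, xout = dives$start_s, rule = 1)$y
  out <- mutate(dives, x = x, y = y,
                bathymetry_m = grid_lookup(grid, x, y, "bathymetry"),
                shore_km = grid_lookup(grid, x, y, "shore_distance"))
  for (extra in intersect(c("slope", "ruggedness", "rugosity"), names(grid$layers))) {
    out[[extra]] <- grid_lookup(grid, x, y, extra)
  }
  if ("habitat" %in% names(grid$layers)) {
    out$habitat <- assign_habitat(grid, x, y, special_polygons)
  }
  dplyr::bind_cols(out, dive_ratio(out$max_depth, out$bathymetry_m))
}

#' Read / write a single raster layer as a plain-text ASCII grid
#'
#' ESRI-style ASCII grid: a header of `ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value` followed by `nrows` rows of values, north row
#' first.
#'
#' @param path File path.
#' @return `read_ascii_grid()`: list `matrix, x0, y0, cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr_keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")
  hdr <- list()
  i <- 1
  while (i <= length(lines)) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2 || !tolower(kv[1]) %in% hdr_keys) break
    hdr[[tolower(kv[1])]] <- kv[2]
    i <- i + 1
  }
  nrows <- as.integer(hdr$nrows); ncols <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = character(), quiet = TRUE)
  nodata <- hdr$nodata_value %||% "-9999"
  numeric_grid <- !any(is.na(suppressWarnings(as.numeric(setdiff(vals, nodata)))))
  if (numeric_grid) {
    vals[vals == nodata] <- NA
    m <- matrix(as.numeric(vals), nrow = nrows, ncol = ncols, byrow = TRUE)
  } else {
    vals[vals == nodata] <- NA
    m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  }
  list(matrix = m, x0 = as.numeric(hdr$xllcorner), y0 = as.numeric(hdr$yllcorner),
       cellsize = as.numeric(hdr$cellsize))
}

#' @rdname read_ascii_grid
#' @param m Layer matrix (row 1 = north).
#' @param x0,y0,cellsize Georeferencing (m).
#' @param nodata NODATA sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(m, path, x0 = 0, y0 = 0, cellsize = 1000,
                             nodata = -9999) {
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %s", format(x0)), sprintf("yllcorner %s", format(y0)),
           sprintf("cellsize %s", format(cellsize)),
           sprintf("NODATA_value %s", format(nodata)))
  body <- apply(m, 1, function(row) {
    row[is.na(row)] <- nodata
    paste(format(row, trim = TRUE, scientific = FALSE), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}
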