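# Internal helpers shared across modules.

#' Derive a child RNG seed from a master seed
#'
#' Deterministic integer hash used to give every seal, trip and chain its own
#' reproducible RNG stream: adding seals or chains never perturbs the streams
#' of earlier ones. Result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed Master seed (single integer).
#' @param ... One or more integer indices (e.g. seal number, chain number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) {
    # multiplicative hash in double precision; all intermediates < 2^53
    x <- (x * 48271 + as.double(k) * 30269 + 11) %% 2147483647
  }
  as.integer(x %% 2147483646) + 1L
}

# Run code with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Stop unless all named columns are present.
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "sealsearch_schema_error")
  }
  invisible(df)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Centred moving average with shrinking (truncated) windows at the edges.
# half-width h in samples; window at i is [i-h, i+h] clipped to [1, n].
moving_average <- function(x, h) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  if (h <= 0) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Maximal runs of TRUE in a logical vector -> tibble(start, end) of indices.
true_runs <- function(mask) {
  n <- length(mask)
  if (n == 0 || !any(mask)) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  tibble(start = starts[keep], end = ends[keep])
}
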