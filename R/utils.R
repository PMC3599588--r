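# Internal helpers.

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Isotropic 2-D Gaussian 1/(2*pi*sigma^2) exp(-r^2 / (2 sigma^2)) sampled on
# the integer grid [-radius, radius]^2 (continuous form; unit integral).
gauss2d <- function(sigma, radius) {
  d <- seq(-radius, radius)
  r2 <- outer(d^2, d^2, "+")
  exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what))
}

# Matrix argmax with row-major tie-breaking (first by row, then by column).
argmax_rowmajor <- function(x) {
  m <- max(x)
  idx <- which(x == m, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  list(row = unname(idx[1L, 1L]), col = unname(idx[1L, 2L]),
       n_ties = nrow(idx))
}

# Normalize a non-negative map to peak 1 (all-zero maps pass through).
norm_peak <- function(x) {
  m <- max(x)
  if (m > 0) x / m else x
}

deg2rad <- function(d) d * pi / 180

# Count strict 8-neighbour local maxima above floor_frac * max(map).
count_local_maxima <- function(x, floor_frac = 0.1) {
  h <- nrow(x); w <- ncol(x)
  if (h < 3L || w < 3L) return(0L)
  core <- x[2:(h - 1L), 2:(w - 1L)]
  is_max <- core > x[1:(h - 2L), 2:(w - 1L)] & core > x[3:h, 2:(w - 1L)] &
    core > x[2:(h - 1L), 1:(w - 2L)] & core > x[2:(h - 1L), 3:w] &
    core > x[1:(h - 2L), 1:(w - 2L)] & core > x[1:(h - 2L), 3:w] &
    core > x[3:h, 1:(w - 2L)] & core > x[3:h, 3:w]
  sum(is_max & core >= floor_frac * max(x))
}
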