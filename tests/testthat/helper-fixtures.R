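# Shared fixtures (built in code, memoized per session) and independent
# brute-force oracles used to cross-check the vectorized implementations.

# --- fixtures ---------------------------------------------------------------

# Small trained basis used by the behavioural tests: 49 filters on a 7x7
# torus, 8x8 patches from the procedural training textures. Cached on disk
# for the session so the training cost is paid once per test run.
test_basis <- function() {
  cache <- file.path(tempdir(), "v1sal_test_basis.rds")
  if (file.exists(cache)) return(readRDS(cache))
  imgs <- gen_texture_images(n_images = 6, size = 128, seed = 42)
  p <- sample_patches(imgs, 8, 20000, seed = 1)
  tf <- fit_whitening(p, 49)
  lc <- learning_config(49, c(7, 7), step_size = 0.5, n_iterations = 800,
                        batch_size = 1000, decay_every = 200, seed = 1)
  b <- backproject_filters(learn_basis(whiten(p, tf), lc), tf)
  b$pool_layout <- refine_pools(build_pools(b), b, 0.1)
  saveRDS(b, cache)
  b
}

# Cheap untrained basis: orthonormal random filters directly in pixel space
# (identity whitening), for mechanical tests that need no learned structure.
pixel_basis <- function(n = 12L, grid = c(3L, 4L), patch = 6L, seed = 99L) {
  d <- patch^2
  cfg <- learning_config(n, grid, neighbourhood_side = 3L, seed = seed)
  b <- init_basis(cfg, d)
  tf <- structure(list(mean_patch = rep(0, d), whitening_matrix = diag(d),
                       dewhitening_matrix = diag(d), retained_dim = d,
                       eigenvalues = rep(1, d), eigenvectors = diag(d),
                       patch_side = patch),
                  class = "whitening_transform")
  backproject_filters(b, tf)
}

# A synthetic conspicuity stack: one informative map with a dominant peak,
# the rest smoothed noise.
informative_stack <- function(n_maps = 10L, h = 64L, w = 64L, peak = c(20L, 44L),
                              noise = 0.3, seed = 1L) {
  set.seed(seed)
  maps <- array(0, c(h, w, n_maps))
  blur <- gauss2d(1.5, 4); blur <- blur / sum(blur)
  for (j in 2:n_maps)
    maps[, , j] <- noise * corr2_same(matrix(runif(h * w), h, w), blur)
  bump <- matrix(0, h, w); bump[peak[1], peak[2]] <- 1
  maps[, , 1] <- corr2_same(bump, gauss2d(2, 6) / max(gauss2d(2, 6))) +
    0.1 * corr2_same(matrix(runif(h * w), h, w), blur)
  structure(list(maps = maps), class = "conspicuity_stack")
}

rand_stack <- function(h, w, n, seed = 1L, rectified = TRUE) {
  set.seed(seed)
  maps <- array(abs(stats::rnorm(h * w * n)), c(h, w, n))
  structure(list(maps = maps, source_shape = c(h, w), rectified = rectified),
            class = "feature_stack")
}

# --- independent oracles ----------------------------------------------------

# Brute-force cross-correlation with mirrored boundary, written index by
# index (independent of the FFT path).
oracle_corr2 <- function(x, k) {
  h <- nrow(x); w <- ncol(x); kr <- nrow(k); kc <- ncol(k)
  cr <- floor(kr / 2) + 1; cc <- floor(kc / 2) + 1
  mirror <- function(i, n) {
    # reflect an out-of-range index back into 1..n (edge repeated)
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (u in seq_len(kr)) for (v in seq_len(kc)) {
      ii <- mirror(i + u - cr, h)
      jj <- mirror(j + v - cc, w)
      acc <- acc + k[u, v] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Per-pixel pooling loop (Eq.-7 oracle).
oracle_pool <- function(maps, idx) {
  h <- dim(maps)[1]; w <- dim(maps)[2]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- sqrt(sum(maps[i, j, idx]^2))
  out
}

# Threshold-sweep ROC area (trapezoidal), independent of the rank-based
# implementation route.
oracle_auc <- function(sal, fix) {
  thr <- sort(unique(as.vector(sal)), decreasing = TRUE)
  thr <- c(Inf, thr, -Inf)
  tpr <- fpr <- numeric(length(thr))
  pos <- sum(fix); neg <- sum(!fix)
  for (k in seq_along(thr)) {
    sel <- sal >= thr[k]
    tpr[k] <- sum(sel & fix) / pos
    fpr[k] <- sum(sel & !fix) / neg
  }
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Population-moment energy correlation (Eq.-6 oracle, explicit moments).
oracle_energy_corr <- function(a, b) {
  a2 <- a^2; b2 <- b^2
  num <- mean(a2 * b2) - mean(a2) * mean(b2)
  den <- sqrt(mean((a2 - mean(a2))^2) * mean((b2 - mean(b2))^2))
  num / den
}

expect_same_matrix <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
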