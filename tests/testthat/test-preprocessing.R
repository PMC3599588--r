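# Patch sampling and PCA whitening.

test_that("sample_patches draws the requested patches and DC-centres them", {
  imgs <- gen_texture_images(n_images = 2, size = 64, seed = 3)
  p <- sample_patches(imgs, 8, 500, seed = 7)
  expect_s3_class(p, "patch_set")
  expect_equal(dim(p$data), c(64L, 500L))
  expect_lt(max(abs(colMeans(p$data))), 1e-12)
  p2 <- sample_patches(imgs, 8, 500, seed = 7)
  expect_identical(p$data, p2$data)
  p3 <- sample_patches(imgs, 8, 500, seed = 8)
  expect_false(identical(p$data, p3$data))
})

test_that("constant images give all-zero patches after DC removal", {
  p <- sample_patches(matrix(0.7, 32, 32), 8, 50, seed = 1)
  expect_equal(max(abs(p$data)), 0)
})

test_that("undersized images are rejected with a warning, all unusable fails", {
  big <- matrix(runif(32 * 32), 32, 32)
  small <- matrix(0, 4, 4)
  expect_warning(p <- sample_patches(list(big, small), 8, 100, seed = 1),
                 "rejected")
  expect_equal(ncol(p$data), 100L)
  expect_error(suppressWarnings(sample_patches(small, 8, 10, seed = 1)),
               "no usable image")
})

test_that("whitening yields identity covariance on the retained components", {
  imgs <- gen_texture_images(n_images = 3, size = 96, seed = 5)
  p <- sample_patches(imgs, 8, 12000, seed = 2)
  tf <- fit_whitening(p, 40)
  expect_equal(dim(tf$whitening_matrix), c(40L, 64L))
  w <- whiten(p, tf)
  cov <- tcrossprod(w$data) / ncol(w$data)
  expect_lt(max(abs(cov - diag(40))), 1e-6)
})

test_that("whitening of isotropic Gaussian patches is near the identity map", {
  set.seed(11)
  d <- 25L; n <- 50000L
  p <- structure(list(data = matrix(rnorm(d * n), d, n), patch_side = 5L,
                      whitened = FALSE), class = "patch_set")
  tf <- fit_whitening(p, d)
  # W should be an approximate rotation: W W' = U^-1 on the eigenbasis, and
  # whitened covariance the identity within sampling error
  cov <- tcrossprod(whiten(p, tf)$data) / n
  expect_lt(max(abs(cov - diag(d))), 1e-2)
  # oracle: explicit eigendecomposition of the empirical covariance
  C <- tcrossprod(p$data - rowMeans(p$data)) / n
  e <- eigen(C, symmetric = TRUE)
  Wo <- (1 / sqrt(e$values)) * t(e$vectors)
  covo <- Wo %*% C %*% t(Wo)
  expect_lt(max(abs(covo - diag(d))), 1e-9)
  expect_lt(max(abs(tf$whitening_matrix %*% C %*% t(tf$whitening_matrix) - diag(d))), 1e-9)
})

test_that("rank-deficient covariance below retained_dim fails, naming the rank", {
  set.seed(12)
  base <- matrix(rnorm(9 * 300), 9, 300)
  base[9, ] <- base[1, ]   # one dependent direction
  p <- structure(list(data = base, patch_side = 3L, whitened = FALSE),
                 class = "patch_set")
  expect_error(fit_whitening(p, 9), "rank 8")
  expect_s3_class(fit_whitening(p, 8), "whitening_transform")
})

test_that("whitening is equivariant under global intensity scaling", {
  imgs <- gen_texture_images(n_images = 2, size = 64, seed = 9)
  p <- sample_patches(imgs, 6, 4000, seed = 3)
  ps <- p; ps$data <- 3.7 * ps$data
  w1 <- whiten(p, fit_whitening(p, 20))$data
  w2 <- whiten(ps, fit_whitening(ps, 20))$data
  # eigenvector signs are arbitrary; compare up to per-component sign
  sgn <- sign(rowSums(w1 * w2))
  expect_lt(max(abs(w1 - sgn * w2)), 1e-6)
})

test_that("whiten-then-dewhiten equals the explicit PCA reconstruction", {
  imgs <- gen_texture_images(n_images = 2, size = 64, seed = 13)
  p <- sample_patches(imgs, 6, 3000, seed = 4)
  k <- 15L
  tf <- fit_whitening(p, k)
  rec <- dewhiten(whiten(p, tf), tf)$data
  # oracle: brute-force projection onto the top-k eigenvectors
  Xc <- p$data - rowMeans(p$data)
  V <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)$vectors[, 1:k]
  rec_o <- V %*% crossprod(V, Xc) + rowMeans(p$data)
  expect_lt(max(abs(rec - rec_o)), 1e-8)
})

test_that("whiten maps the zero patch to zero and rejects dimension mismatch", {
  imgs <- gen_texture_images(n_images = 2, size = 64, seed = 15)
  p <- sample_patches(imgs, 6, 2000, seed = 5)
  tf <- fit_whitening(p, 12)
  tf0 <- tf; tf0$mean_patch <- rep(0, 36)   # pure linear map
  z <- p; z$data <- matrix(0, 36, 3)
  expect_equal(max(abs(whiten(z, tf0)$data)), 0)
  bad <- p; bad$data <- matrix(0, 25, 3)
  expect_error(whiten(bad, tf), "dimension")
})
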