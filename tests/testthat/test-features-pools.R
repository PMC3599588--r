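# Layer-1 extraction, rectification, pool construction/refinement, pooling.

test_that("a filter embedded in zeros peaks at its location with its self-correlation", {
  b <- pixel_basis(patch = 6)
  img <- matrix(0, 40, 40)
  f <- matrix(b$pixel_filters[5, ], 6, 6)
  img[17:22, 11:16] <- f
  st <- extract_features(img, b)
  m <- st$maps[, , 5]
  am <- which(m == max(m), arr.ind = TRUE)[1, ]
  # kernel centre for a 6x6 filter sits at offset (4,4) inside the patch
  expect_equal(unname(am), c(17 + 3, 11 + 3))
  expect_equal(max(m), sum(f * f) / sqrt(sum(f^2)), tolerance = 1e-9)
})

test_that("zero image gives all-zero maps; undersized image fails", {
  b <- pixel_basis(patch = 6)
  st <- extract_features(matrix(0, 20, 20), b)
  expect_equal(max(abs(st$maps)), 0)
  expect_equal(dim(st$maps), c(20L, 20L, 12L))
  expect_error(extract_features(matrix(0, 4, 4), b), "smaller")
})

test_that("rectification is even, zero-preserving, and bounded in [0, 1)", {
  set.seed(51)
  x <- rnorm(100, sd = 3)
  st <- structure(list(maps = array(x, c(10, 10, 1)), source_shape = c(10, 10),
                       rectified = FALSE), class = "feature_stack")
  stn <- structure(list(maps = array(-x, c(10, 10, 1)), source_shape = c(10, 10),
                        rectified = FALSE), class = "feature_stack")
  r <- rectify(st); rn <- rectify(stn)
  expect_equal(r$maps, rn$maps)                     # even in the input
  expect_equal(r$maps, 2 / (1 + exp(-abs(st$maps))) - 1)
  expect_true(all(r$maps >= 0 & r$maps < 1))
  z <- st; z$maps[] <- 0
  expect_equal(max(abs(rectify(z)$maps)), 0)        # zero-preserving
  expect_gt(min(rectify(z, mode = "logistic")$maps), 0.49)
  big <- st; big$maps[] <- 50
  expect_gt(min(rectify(big)$maps), 1 - 1e-9)       # saturation at 1
})

test_that("build_pools reproduces the printed bases-to-pools pairs", {
  cases <- list(c(10, 10, 16), c(14, 14, 25), c(14, 28, 50),
                c(24, 24, 64), c(16, 16, 36))
  for (cs in cases) {
    layout <- build_pools(c(cs[1], cs[2]), pool_side = 5, overlap = 2)
    expect_length(layout$pools, cs[3])
    expect_true(all(lengths(layout$pools) == 25L))
    for (j in seq_along(layout$pools))
      expect_true(layout$center_index[j] %in% layout$pools[[j]])
  }
  expect_error(build_pools(c(4, 4), pool_side = 5), "exceeds")
  expect_error(build_pools(c(10, 10), pool_side = 4), "odd")
})

test_that("pool similarity: self is 1, scaling is invariant, independence is near 0", {
  set.seed(61)
  st <- rand_stack(50, 50, 3, seed = 61)
  expect_equal(pool_similarity(st, 1, 1), 1)
  st$maps[, , 2] <- 2 * st$maps[, , 1]
  expect_equal(pool_similarity(st, 1, 2), 1, tolerance = 1e-12)
  big <- rand_stack(320, 320, 2, seed = 62)   # ~1e5 independent samples
  expect_lt(abs(pool_similarity(big, 1, 2)), 0.05)
  # matches the explicit-moment oracle
  expect_equal(pool_similarity(st, 1, 3),
               oracle_energy_corr(as.vector(st$maps[, , 1]),
                                  as.vector(st$maps[, , 3])),
               tolerance = 1e-12)
})

test_that("zero-variance responses give similarity 0 with a warning", {
  st <- rand_stack(10, 10, 2, seed = 63)
  st$maps[, , 2] <- 1
  expect_warning(s <- pool_similarity(st, 1, 2), "zero variance")
  expect_equal(s, 0)
})

test_that("refinement bounds: threshold -1 keeps pools, threshold >1 keeps centres", {
  b <- test_basis()
  layout <- build_pools(b)
  lo <- refine_pools(layout, b, -1)
  expect_identical(lapply(lo$pools, sort), lapply(layout$pools, sort))
  hi <- refine_pools(layout, b, 1 + 1e-9)
  expect_true(all(lengths(hi$pools) == 1L))
  expect_equal(unlist(hi$pools), layout$center_index)
  expect_error(refine_pools(hi, b, 0.1), "already refined")
})

test_that("pooling matches the per-pixel oracle and its energy form exactly", {
  st <- rand_stack(12, 14, 6, seed = 71)
  layout <- build_pools(c(2, 3), pool_side = 1, overlap = 0)
  layout$pools <- list(c(1L, 3L, 5L), 2L, c(4L, 6L))
  layout$center_index <- c(1L, 2L, 4L)
  inv <- pool_features(st, layout)
  for (j in 1:3)
    expect_same_matrix(inv$maps[, , j], oracle_pool(st$maps, layout$pools[[j]]),
                       tol = 1e-12)
  # energy form: CF^2 = sum SF^2
  expect_same_matrix(inv$maps[, , 1]^2,
                     st$maps[, , 1]^2 + st$maps[, , 3]^2 + st$maps[, , 5]^2,
                     tol = 1e-12)
  # single-member pool passes through; zero members give zero
  expect_same_matrix(inv$maps[, , 2], st$maps[, , 2], tol = 1e-12)
  z <- st; z$maps[3, 7, ] <- 0
  expect_equal(pool_features(z, layout)$maps[3, 7, ], rep(0, 3))
})

test_that("adding a member to a pool never decreases the pooled map", {
  st <- rand_stack(9, 9, 5, seed = 72)
  layout <- build_pools(c(1, 2), pool_side = 1, overlap = 0)
  layout$pools <- list(c(1L, 2L), c(1L, 2L, 4L))
  layout$center_index <- c(1L, 1L)
  inv <- pool_features(st, layout)
  expect_true(all(inv$maps[, , 2] >= inv$maps[, , 1]))
})

test_that("pooling smooths orientation: invariant maps change less than the best filter map", {
  b <- test_basis()
  bar <- function(theta) {
    segs <- tibble::tibble(id = 1L, is_object = TRUE, cx = 32, cy = 32,
                           theta = theta, length = 20, width = 3)
    render_segments(segs, c(64L, 64L))$image
  }
  rel_change <- function(m1, m2) sqrt(sum((m1 - m2)^2)) / sqrt(sum(m1^2))
  layout <- b$pool_layout
  worst <- c()
  for (theta in c(0, 40, 90, 130)) {
    f1 <- rectify(extract_features(bar(theta), b))
    f2 <- rectify(extract_features(bar(theta + 5), b))
    i1 <- pool_features(f1, layout); i2 <- pool_features(f2, layout)
    # strongest-responding single filter map vs its pooled counterpart
    peak <- which.max(apply(f1$maps, 3, max))
    sf_change <- rel_change(f1$maps[, , peak], f2$maps[, , peak])
    pj <- which.max(apply(i1$maps, 3, max))
    cf_change <- rel_change(i1$maps[, , pj], i2$maps[, , pj])
    worst <- c(worst, cf_change < sf_change)
  }
  expect_gte(mean(worst), 0.75)
})
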