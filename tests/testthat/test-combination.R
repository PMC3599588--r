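# Saliency-map combination strategies.

test_that("iteration strengthens an initial maximum against weak noise", {
  set.seed(91)
  m <- matrix(0.1 * runif(64 * 64), 64, 64)
  m[32, 32] <- 1
  p <- combine_params(n_iterations = 5)
  out <- iterate_map(m, p)
  bg <- function(x) mean(x[-which.max(x)])    # all non-peak pixels
  expect_equal(unname(which(out == max(out), arr.ind = TRUE)[1, ]), c(32, 32))
  expect_gt(max(out) / bg(out), max(m) / bg(m))
})

test_that("all-zero maps stay zero; zero kernel with zero bias is the identity", {
  p <- combine_params(n_iterations = 3)
  z <- matrix(0, 20, 20)
  expect_equal(iterate_map(z, p), z)
  set.seed(92)
  m <- matrix(abs(rnorm(100)), 10, 10)
  p0 <- combine_params(n_iterations = 4, C_inh = 0)
  expect_same_matrix(iterate_map(m, p0, kernel = matrix(0, 5, 5)), m, 1e-12)
  expect_error(iterate_map(matrix(NaN, 5, 5), p), "non-finite")
})

test_that("sum and max combinations match their per-pixel oracles", {
  st <- informative_stack(4, 32, 32, peak = c(10, 20), seed = 3)
  s <- combine_sum(st); mx <- combine_max(st)
  nrm <- st$maps
  for (j in 1:4) nrm[, , j] <- nrm[, , j] / max(nrm[, , j])
  so <- matrix(0, 32, 32); mo <- matrix(-Inf, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    so[i, j] <- sum(nrm[i, j, ])
    mo[i, j] <- max(nrm[i, j, ])
  }
  expect_same_matrix(unclass(s), so, 1e-12)
  expect_same_matrix(unclass(mx), mo, 1e-12)
  expect_true(all(unclass(mx) >= nrm[, , 2]))
  # single map: sum and max reduce to the normalized map
  one <- structure(list(maps = st$maps[, , 1, drop = FALSE]),
                   class = "conspicuity_stack")
  expect_same_matrix(unclass(combine_sum(one)), st$maps[, , 1] / max(st$maps[, , 1]), 1e-12)
  # two identical maps sum to twice one map
  two <- structure(list(maps = st$maps[, , c(1, 1)]), class = "conspicuity_stack")
  expect_same_matrix(unclass(combine_sum(two)), 2 * st$maps[, , 1] / max(st$maps[, , 1]), 1e-12)
})

test_that("strategies commute with map reordering", {
  st <- informative_stack(6, 32, 32, peak = c(16, 16), seed = 4)
  perm <- c(4, 1, 6, 2, 5, 3)
  stp <- structure(list(maps = st$maps[, , perm]), class = "conspicuity_stack")
  expect_equal(unclass(combine_sum(st)), unclass(combine_sum(stp)))
  expect_equal(unclass(combine_max(st)), unclass(combine_max(stp)))
  p <- combine_params(n_iterations = 3)
  expect_equal(unclass(combine_iterate(st, p)), unclass(combine_iterate(stp, p)),
               tolerance = 1e-12)
  p2 <- combine_params(n_iterations = 2, n_clusters = 2, seed = 5)
  expect_equal(unclass(combine_clustered(st, p2)),
               unclass(combine_clustered(stp, p2)), tolerance = 1e-10)
})

test_that("iteration yields sparser maps than summation and finds the true peak", {
  st <- informative_stack(10, 64, 64, peak = c(20, 44), seed = 7)
  cmp <- combine_compare(st, combine_params(seed = 7))
  frac <- function(s) cmp$active_fraction[cmp$strategy == s]
  expect_lt(frac("iterate"), frac("sum"))
  it_map <- attr(cmp, "maps")$iterate
  am <- which(unclass(it_map) == max(it_map), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(am - c(20, 44))), 2)
  # max combination keeps many spurious local maxima
  expect_gte(cmp$n_local_maxima[cmp$strategy == "max"], 3)
})

test_that("clustered combination recovers duplicated map groups exactly", {
  set.seed(8)
  base1 <- corr2_same(matrix(runif(900), 30, 30), gauss2d(2, 5))
  base2 <- corr2_same(matrix(runif(900), 30, 30), gauss2d(2, 5))
  maps <- array(0, c(30, 30, 6))
  grp <- c(1, 2, 1, 1, 2, 2)
  for (j in 1:6)
    maps[, , j] <- (if (grp[j] == 1) base1 else base2) * runif(1, 0.8, 1.2)
  sim <- map_similarity(maps, 1L)
  # oracle: exhaustive best 2-partition by within-cluster similarity
  best <- NULL; best_score <- -Inf
  for (mask in 1:(2^6 - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:5)))
    if (sum(g) == 0 || sum(g) == 6) next
    score <- mean(sim[g, g]) + mean(sim[!g, !g])
    if (score > best_score) { best_score <- score; best <- g }
  }
  expect_true(all(best == (grp == grp[which(best)[1]])))
  km <- with_seed(11L, stats::kmeans(sim, centers = 2, nstart = 10L))$cluster
  expect_true(all((km == km[1]) == (grp == grp[1])))
})

test_that("clustered with as many clusters as maps equals plain iteration", {
  st <- informative_stack(5, 24, 24, peak = c(12, 12), seed = 9)
  p <- combine_params(n_iterations = 3, n_clusters = 5, seed = 1)
  expect_same_matrix(combine_clustered(st, p), combine_iterate(st, p), 1e-10)
  expect_error(combine_clustered(informative_stack(3, 24, 24, peak = c(12, 12),
                                                   seed = 2),
                                 combine_params(n_clusters = 8)),
               "fewer maps than clusters")
  expect_error(combine_iterate(structure(list(maps = array(0, c(4, 4, 0))),
                                         class = "conspicuity_stack")),
               "empty")
})
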