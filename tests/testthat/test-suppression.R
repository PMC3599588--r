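# DoG kernel, inhibition weights, and surround suppression.

px_params <- function(sigma_ex = 2, sigma_inh = 8, alpha = 1.8, ...)
  suppression_params(sigma_ex, sigma_inh, alpha = alpha, unit = "px", ...)

test_that("DoG has the closed-form centre value, radial symmetry, and near-zero sum", {
  p <- px_params()
  k <- dog_kernel(p)
  r <- p$kernel_radius
  expect_equal(dim(k), c(2 * r + 1, 2 * r + 1))
  expect_equal(k[r + 1, r + 1],
               1 / (2 * pi * 4) - 1 / (2 * pi * 64), tolerance = 1e-12)
  # both Gaussian terms have unit continuous integral; the 3-sigma_inh square
  # window keeps all but ~0.3% of the inhibitory mass, so the discrete sum is
  # the small positive truncation residue
  expect_lt(abs(sum(k)), 5e-3)
  # quarter-turn symmetry: value at (x, y) equals value at (-y, x)
  expect_equal(k, t(k[, (2 * r + 1):1]))
  expect_gt(k[r + 1, r + 1], 0)
  expect_lt(k[r + 1, 1], 0)                       # annulus is negative
  expect_error(suppression_params(8, 2, unit = "px"), "sigma_inh > sigma_ex")
})

test_that("inhibition weights are the L1-normalized DoG under each convention", {
  p <- px_params()            # default "abs": unit mass
  w <- inhibition_weights(p)
  k <- dog_kernel(p)
  expect_true(all(w >= 0))
  expect_equal(w, abs(k) / sum(abs(k)))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  wc <- inhibition_weights(px_params(convention = "center"))
  expect_equal(wc, pmax(k, 0) / sum(abs(k)))
  expect_equal(min(wc), 0)                       # zero on the annulus
  expect_gt(sum(wc), 0); expect_lt(sum(wc), 1)
  wa <- inhibition_weights(px_params(convention = "annulus"))
  expect_equal(wa, pmax(-k, 0) / sum(abs(k)))
  # normalization is invariant to rescaling the DoG
  expect_equal(abs(3 * k) / sum(abs(3 * k)), w)
})

test_that("unit conversion resolves rf and image-fraction sigmas", {
  p <- resolve_suppression(suppression_params(sigma_ex = 2), rf_size = 8)
  expect_equal(p$sigma_ex, 16); expect_equal(p$sigma_inh, 64)
  expect_equal(p$kernel_radius, 192)
  pf <- resolve_suppression(suppression_params(sigma_ex = 0.02, unit = "frac"),
                            image_shape = c(200, 300))
  expect_equal(pf$sigma_ex, 6)
  expect_error(resolve_suppression(suppression_params(sigma_ex = 2)), "rf_size")
})

test_that("suppress: alpha 0 is the identity; constant maps follow the closed form", {
  set.seed(81)
  m <- matrix(abs(rnorm(40 * 40)), 40, 40)
  p0 <- px_params(alpha = 0)
  expect_same_matrix(suppress(m, p0), m, tol = 1e-10)
  # constant input: s = max(C * (1 - alpha * sum(omega)), 0) away from borders
  p <- px_params(alpha = 3)
  w <- inhibition_weights(p)
  cst <- matrix(0.6, 80, 80)
  s <- suppress(cst, p)
  expect_equal(s[40, 40], max(0.6 * (1 - 3 * sum(w)), 0), tolerance = 1e-9)
  if (3 * sum(w) >= 1) expect_lt(max(s[30:50, 30:50]), 1e-9)
})

test_that("an isolated peak survives suppression", {
  p <- px_params()
  m <- matrix(0, 60, 60); m[30, 30] <- 1
  s <- suppress(m, p)
  w <- inhibition_weights(p)
  c0 <- (dim(w) + 1) %/% 2
  expect_gte(s[30, 30], (1 - p$alpha * w[c0[1], c0[2]]) - 1e-9)
  expect_equal(unname(which(s == max(s), arr.ind = TRUE)[1, ]), c(30, 30))
})

test_that("suppression matches the brute-force oracle on small maps", {
  set.seed(82)
  p <- px_params(sigma_ex = 1, sigma_inh = 3, alpha = 1.5)
  w <- inhibition_weights(p)
  for (rep in 1:3) {
    m <- matrix(abs(rnorm(25 * 30)), 25, 30)
    expect_same_matrix(suppress(m, p),
                       pmax(m - 1.5 * oracle_corr2(m, w), 0), tol = 1e-9)
  }
})

test_that("conspicuity stacks are non-negative and match per-map suppression", {
  st <- rand_stack(30, 30, 4, seed = 83)
  p <- px_params(sigma_ex = 1.5, sigma_inh = 5)
  cs <- conspicuity_stack(st, p)
  expect_true(all(cs$maps >= 0))
  for (j in 1:4)
    expect_same_matrix(cs$maps[, , j], suppress(st$maps[, , j], p), tol = 1e-10)
})

test_that("orientation singleton pops out across the tested alpha range", {
  b <- test_basis()
  scene <- gen_orientation_array(noise_halfwidth = 0, seed = 301)
  feats <- rectify(extract_features(scene$image, b))
  inv <- pool_features(feats, b$pool_layout)
  tgt <- which(scene$target_mask, arr.ind = TRUE)
  tr <- round(mean(tgt[, 1])); tc <- round(mean(tgt[, 2]))
  dist_px <- which(scene$segment_labels > 0 & !scene$target_mask)
  for (alpha in c(1.2, 2.2, 3.2)) {
    p <- resolve_suppression(suppression_params(alpha = alpha), rf_size = 8)
    cs <- conspicuity_stack(inv, p)
    popped <- vapply(seq_len(dim(cs$maps)[3]), function(j) {
      m <- cs$maps[, , j]
      max(m[(tr - 4):(tr + 4), (tc - 4):(tc + 4)]) > stats::median(m[dist_px])
    }, logical(1))
    expect_true(any(popped))
  }
})

test_that("excitation bandwidth below the RF size degrades pop-out detection", {
  b <- test_basis()
  comb <- combine_params()
  rate <- function(sigma_ex) {
    hits <- 0
    for (i in 1:6) {
      scene <- gen_orientation_array(noise_halfwidth = 0, seed = 400 + i)
      map <- run_variant(scene$image, b, variant_spec("invariant"),
                         suppression_params(sigma_ex = sigma_ex), comb)
      hits <- hits + suppressWarnings(detect_target(map, scene)$hit)
    }
    hits / 6
  }
  expect_lte(rate(0.35), rate(2))
})
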