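# Stimulus generators and their ground truth.

test_that("orientation arrays have orthogonal distractors and consistent truth", {
  sc <- gen_orientation_array(noise_halfwidth = 0, seed = 5)
  expect_s3_class(sc, "scene")
  expect_equal(dim(sc$image), c(256L, 256L))
  expect_equal(nrow(sc$segments), 64L)
  expect_equal(sum(sc$segments$is_object), 1L)
  expect_gt(sum(sc$target_mask), 0)
  tt <- sc$params$theta_target
  dd <- sc$segments$theta[!sc$segments$is_object]
  delta <- (dd - tt) %% 180
  expect_true(all(abs(delta - 90) < 1e-9))
  # target mask only covers the object segment
  tgt_id <- sc$segments$id[sc$segments$is_object]
  expect_true(all(sc$segment_labels[sc$target_mask] == tgt_id))
})

test_that("orientation noise stays inside the requested band", {
  sc <- gen_orientation_array(noise_halfwidth = 30, seed = 6)
  tt <- sc$params$theta_target
  dd <- sc$segments$theta[!sc$segments$is_object]
  delta <- (dd - tt) %% 180
  expect_true(all(delta >= 60 - 1e-9 & delta <= 120 + 1e-9))
  expect_gt(stats::sd(delta), 1)   # noise actually applied
  expect_error(gen_orientation_array(noise_halfwidth = 50), "45")
  expect_error(gen_orientation_array(spacing = 8L, bar_length = 16), "overlap")
})

test_that("generators are pure functions of parameters and seed", {
  a <- gen_orientation_array(noise_halfwidth = 20, seed = 9)
  b <- gen_orientation_array(noise_halfwidth = 20, seed = 9)
  expect_identical(a$image, b$image)
  expect_identical(a$segments, b$segments)
  c <- gen_orientation_array(noise_halfwidth = 20, seed = 10)
  expect_false(identical(a$image, c$image))
  d1 <- gen_object_in_texture("pear", "brick", seed = 4)
  d2 <- gen_object_in_texture("pear", "brick", seed = 4)
  expect_identical(d1$image, d2$image)
})

test_that("composite arrays contain exactly the requested deviants", {
  sc <- gen_composite_array(n_deviant = 1, seed = 11)
  expect_equal(length(unique(sc$segments$id[sc$segments$is_object])), 1L)
  expect_gt(sum(sc$target_mask), 0)
  expect_equal(length(unique(sc$segments$id)), 64L)   # element count = grid
  sc0 <- gen_composite_array(n_deviant = 0, seed = 12)
  expect_equal(sum(sc0$target_mask), 0)
  expect_false(sc0$params$has_target)
})

test_that("contour elements align with the analytic path tangent", {
  sc <- gen_contour_scene("illusory_s", seed = 13)
  obj <- sc$segments[sc$segments$is_object, ]
  p <- s_path(obj$t, dim(sc$image))
  dtheta <- (obj$theta - p$theta) %% 180
  dtheta <- pmin(dtheta, 180 - dtheta)
  expect_lt(max(dtheta), 1)
  solid <- gen_contour_scene("solid_s", seed = 13)
  expect_true(all(solid$segments$is_object))
  expect_true(all(solid$target_mask == (solid$segment_labels > 0)))
})

test_that("noisy contour at zero background density equals the illusory contour", {
  a <- gen_contour_scene("noisy_s", background_density = 0, seed = 14)
  b <- gen_contour_scene("illusory_s", seed = 14)
  expect_equal(a$image, b$image)
  n <- gen_contour_scene("noisy_s", background_density = 8e-4, seed = 14)
  expect_gt(sum(!n$segments$is_object), 0)
})

test_that("object-in-texture SNR arithmetic holds and truth is consistent", {
  sc <- gen_object_in_texture("banana", "wave", snr_ratio = 3, seed = 15)
  expect_equal(sc$params$n, round(sc$params$m * 3))
  expect_equal(sum(sc$segments$is_object), sc$params$m)
  expect_equal(sum(!sc$segments$is_object), sc$params$n)
  sc1 <- gen_object_in_texture("onion", "cross", snr_ratio = 1, seed = 16)
  expect_equal(sc1$params$n, sc1$params$m)
  # target mask covered by object-labelled pixels only
  obj_ids <- sc$segments$id[sc$segments$is_object]
  expect_true(all(sc$segment_labels[sc$target_mask] %in% obj_ids))
  # object segments stay in the central region
  obj <- sc$segments[sc$segments$is_object, ]
  expect_true(all(obj$cx > 16 & obj$cx < 48 & obj$cy > 16 & obj$cy < 48))
  expect_error(gen_object_in_texture("pear", "brick", snr_ratio = 50, seed = 1),
               "offers")
})

test_that("every object/texture pair renders with roughly 30 object segments", {
  for (ob in c("pear", "banana", "onion")) for (tx in c("brick", "diag", "arc")) {
    sc <- gen_object_in_texture(ob, tx, snr_ratio = 2, seed = 17)
    expect_gte(sc$params$m, 25)
    expect_lte(sc$params$m, 35)
    expect_gt(sum(sc$image), 0)
  }
})

test_that("training textures are reproducible images in [0, 1]", {
  t1 <- gen_texture_images(n_images = 2, size = 64, seed = 20)
  t2 <- gen_texture_images(n_images = 2, size = 64, seed = 20)
  expect_identical(t1, t2)
  expect_true(all(vapply(t1, function(m) min(m) >= 0 && max(m) <= 1, logical(1))))
  expect_gt(stats::sd(t1[[1]]), 0.05)
})
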