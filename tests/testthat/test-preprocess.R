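test_that("clamp/scale maps HU into [-1, 1] with the stated fixed points", {
  p <- normalization_params()
  g <- image_grid(c(6, 1, 1), c(1, 1, 1))
  v <- volume(array(c(800, 2000, 0, 400, -2000, -800), c(6, 1, 1)), g)
  out <- clamp_scale(v, p)
  expect_equal(out$modality, "NORMALIZED")
  expect_equal(as.vector(out$values), c(1, 1, 0, 0.5, -1, -1))

  set.seed(1)
  any_hu <- volume(array(stats::rnorm(6^3, 0, 2000), c(6, 6, 6)),
                   image_grid(c(6, 6, 6), c(1, 1, 1)))
  nv <- clamp_scale(any_hu, p)
  expect_true(all(nv$values >= -1 & nv$values <= 1))
  # idempotence after the first application
  expect_equal(clamp_scale(nv, p)$values, nv$values)
  # monotone non-decreasing
  x <- sort(stats::rnorm(100, 0, 1000))
  expect_true(all(diff(clamp_scale(x, p)) >= 0))
})

test_that("normalisation parameter invariants are enforced", {
  expect_error(normalization_params(clamp_low = 800, clamp_high = -800), "<")
  expect_error(normalization_params(scale = 0), "> 0")
})

test_that("trilinear resampling preserves constants, identity and linear ramps", {
  g <- image_grid(c(10, 10, 10), c(2, 2, 4))
  const <- volume(array(60, g$shape), g)
  out <- resample_image(const, c(1.36, 1.36, 3))
  expect_true(all(abs(out$values - 60) < 1e-9))
  expect_equal(out$grid$spacing, c(1.36, 1.36, 3))

  same <- resample_image(const, c(2, 2, 4))
  expect_identical(same$values, const$values)

  # linear ramp along z: interpolation is exact for affine signals
  ramp <- volume(array(rep(seq(0, 36, by = 4), each = 100), g$shape), g)
  half <- resample_image(ramp, c(2, 2, 2))
  zpos <- (seq_len(half$grid$shape[3]) - 1) * 2
  expected <- pmin(zpos, 36)   # clamped at the last voxel centre
  expect_equal(as.vector(half$values[5, 5, ]), expected, tolerance = 1e-12)

  expect_error(resample_image(const, c(0, 1, 1)), "positive")
})

test_that("label resampling is nearest-neighbour and closed over input labels", {
  g <- image_grid(c(8, 8, 8), c(2, 2, 2))
  lab <- array(0L, g$shape); lab[4, 5, 6] <- 7L
  lm <- label_map(lab, g)
  expect_identical(resample_labels_back(lm, g)$labels, lm$labels)

  fine <- image_grid(c(16, 16, 16), c(1, 1, 1), origin = c(-0.5, -0.5, -0.5))
  up <- resample_labels_back(lm, fine)
  expect_equal(sum(up$labels == 7L), 8L)   # one voxel becomes a 2x2x2 block
  expect_true(all(unique(as.vector(up$labels)) %in% c(0L, 7L)))

  far <- image_grid(c(4, 4, 4), c(1, 1, 1), origin = c(1000, 0, 0))
  expect_error(resample_labels_back(lm, far), "overlap")
})

test_that("round-trip resampling of a smooth phantom stays within interpolation error", {
  g <- image_grid(c(24, 24, 24), c(2, 2, 2))
  co <- (seq_len(24) - 1) * 2
  smooth <- outer(outer(sin(co / 8), cos(co / 10), `+`), sin(co / 12), `+`) * 100
  v <- volume(smooth, g)
  down_up <- resample_image(resample_image(v, c(3, 3, 3)), c(2, 2, 2))
  core <- 5:19   # away from edge-clamping effects
  err <- abs(down_up$values[core, core, core] - v$values[core, core, core])
  expect_lt(max(err), 6)   # second-order interpolation error bound at h = 3 mm
})

test_that("patch sampling honours annotation masks, determinism, and padding", {
  tr <- tiny_phantom()
  set.seed(5)
  p_full <- sample_patch(tr$ct, tr$labels, NULL, c(10, 10, 10))
  expect_true(all(p_full$mask == 1))
  expect_equal(dim(p_full$image), c(10, 10, 10))

  ann <- annotation_mask(2L)   # label 1 unannotated
  set.seed(6)
  p <- sample_patch(tr$ct, tr$labels, ann, c(16, 16, 12), fg_bias = 1)
  expect_true(all(p$mask[p$labels == 1L] == 0))
  expect_true(all(p$mask[p$labels != 1L] == 1))

  set.seed(9); a <- sample_patch(tr$ct, tr$labels, NULL, c(8, 8, 8))
  set.seed(9); b <- sample_patch(tr$ct, tr$labels, NULL, c(8, 8, 8))
  expect_identical(a$image, b$image)
  expect_identical(a$origin0, b$origin0)

  # volume smaller than the patch: mirror-padded, shape still honoured
  set.seed(2)
  pp <- sample_patch(tr$ct, tr$labels, NULL, c(20, 20, 20))
  expect_equal(dim(pp$image), c(20, 20, 20))
})

test_that("augmentation draws stay inside the stated ranges and compose with clamping", {
  tr <- tiny_phantom()
  set.seed(3)
  patch <- sample_patch(tr$ct, tr$labels, NULL, c(12, 12, 12))

  zero <- augmentation_params(0, 0, 0)
  out <- augment(patch, zero)
  expect_identical(out$image, patch$image)
  expect_identical(out$labels, patch$labels)

  set.seed(4)
  draws <- t(replicate(2000, attr(augment(patch, augmentation_params()), "draws")))
  expect_true(all(abs(draws[, "rotation"]) <= 0.15))
  expect_true(all(draws[, "scale"] >= 0.9 & draws[, "scale"] <= 1.1))
  expect_true(all(abs(draws[, "shift"]) <= 100))

  # +100 HU on an 800 HU voxel still normalises to 1.0
  expect_equal(clamp_scale(800 + 100, normalization_params()), 1.0)

  # geometric transforms hit image and labels identically (nearest-voxel)
  set.seed(8)
  ao <- augment(patch, augmentation_params(0.15, 0.1, 0))
  expect_equal(dim(ao$labels), dim(patch$labels))
  expect_true(all(unique(as.vector(ao$labels)) %in%
                    unique(as.vector(patch$labels))))
})

test_that("threshold mask selects exactly the requested HU range", {
  tr <- tiny_phantom(noise_sd = 0)
  all_on <- threshold_mask(tr$ct, c(-Inf, Inf))
  expect_true(all(all_on))
  bone <- threshold_mask(tr$ct, c(200, 1500))
  expect_identical(bone, tr$labels$labels == 2L)
  none <- threshold_mask(tr$ct, c(10.2, 10.4))
  expect_false(any(none))
  expect_error(threshold_mask(tr$ct, c(5, -5)), "<=")
  # region intersection
  reg <- array(FALSE, tr$ct$grid$shape); reg[1:4, , ] <- TRUE
  expect_true(all(which(threshold_mask(tr$ct, c(200, 1500), reg), arr.ind = TRUE)[, 1] <= 4))
})
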