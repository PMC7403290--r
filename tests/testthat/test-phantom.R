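test_that("noiseless phantom construction is exact and deterministic", {
  t1 <- tiny_phantom(seed = 7, noise_sd = 0)
  t2 <- tiny_phantom(seed = 7, noise_sd = 0)
  expect_identical(t1$ct$values, t2$ct$values)
  expect_identical(t1$labels$labels, t2$labels$labels)
  # every organ voxel carries exactly the primitive HU; background is air
  expect_true(all(t1$ct$values[t1$labels$labels == 1L] == 60))
  expect_true(all(t1$ct$values[t1$labels$labels == 2L] == 700))
  expect_true(all(t1$ct$values[t1$labels$labels == 0L] == -1000))
})

test_that("later primitives overwrite earlier ones at overlaps", {
  grid <- image_grid(c(10, 10, 10), c(2, 2, 2))
  organs <- list(
    list(label = 1L, shape = "box", centre_mm = c(9, 9, 9),
         radii_mm = c(6, 6, 6), hu_mean = 100),
    list(label = 2L, shape = "box", centre_mm = c(9, 9, 9),
         radii_mm = c(3, 3, 3), hu_mean = 300))
  tr <- generate_phantom(phantom_spec(grid, organs, noise_sd = 0))
  expect_true(all(tr$ct$values[tr$labels$labels == 2L] == 300))
  expect_true(any(tr$labels$labels == 1L))
})

test_that("primitives outside the grid are rejected", {
  grid <- image_grid(c(8, 8, 8), c(2, 2, 2))
  organs <- list(list(label = 1L, shape = "ellipsoid", centre_mm = c(40, 8, 8),
                      radii_mm = c(4, 4, 4), hu_mean = 50))
  expect_error(phantom_spec(grid, organs), "outside")
})

test_that("spine phantoms carry one centre per vertebra, equal to the mask centroid", {
  tr <- desk_spine_phantom(seed = 3, n_vertebrae = 5)
  ic <- tr$instance_centres
  expect_equal(nrow(ic), 5L)
  expect_equal(sort(unique(as.vector(tr$instance_id))), 0:5)
  g <- tr$ct$grid
  for (i in ic$id) {
    m <- tr$instance_id == i
    idx <- which(m, arr.ind = TRUE) - 1
    cen <- colMeans(sweep(sweep(idx, 2, g$spacing, `*`), 2, g$origin, `+`))
    stored <- unlist(ic[ic$id == i, c("cx", "cy", "cz")], use.names = FALSE)
    expect_true(all(abs(stored - cen) <= g$spacing / 2))
  }
})

test_that("phantom geometry is scale-consistent across resolutions", {
  grid_hi <- image_grid(c(32, 32, 32), c(2, 2, 2))
  grid_lo <- image_grid(c(16, 16, 16), c(4, 4, 4))
  organs <- list(list(label = 1L, shape = "ellipsoid", centre_mm = c(31, 31, 31),
                      radii_mm = c(16, 12, 10), hu_mean = 50))
  hi <- generate_phantom(phantom_spec(grid_hi, organs, noise_sd = 0))
  lo <- generate_phantom(phantom_spec(grid_lo, organs, noise_sd = 0))
  # fractional organ volume agrees between resolutions
  f_hi <- mean(hi$labels$labels == 1L)
  f_lo <- mean(lo$labels$labels == 1L)
  expect_lt(abs(f_hi - f_lo) / f_hi, 0.15)
})

test_that("PET generation matches requested uptake exactly (noiseless) and by CLT (noisy)", {
  tr <- tiny_phantom(noise_sd = 0)
  pet0 <- generate_pet(tr, c(`1` = 5), noise_sd = 0)
  expect_true(all(pet0$values[tr$labels$labels == 1L] == 5))
  expect_true(all(pet0$values[tr$labels$labels != 1L] == 0))

  expect_true(all(generate_pet(tr, c(`1` = 0, `2` = 0), noise_sd = 0)$values == 0))

  big <- generate_phantom(phantom_spec(
    image_grid(c(32, 32, 32), c(2, 2, 2)),
    list(list(label = 1L, shape = "box", centre_mm = c(31, 31, 31),
              radii_mm = c(24, 24, 24), hu_mean = 0)),
    noise_sd = 0, seed = 2))
  n <- sum(big$labels$labels == 1L)
  expect_gt(n, 1e4)
  pet <- generate_pet(big, c(`1` = 5), noise_sd = 0.5, seed = 11)
  m <- mean(pet$values[big$labels$labels == 1L])
  expect_lt(abs(m - 5), 3 * 0.5 / sqrt(n))

  expect_error(generate_pet(tr, c(`1` = -2)), "non-negative")
})

test_that("annotation sparsification is a valid Bernoulli thinning", {
  tr <- tiny_phantom()
  expect_equal(sparsify_annotation(tr, 1)$annotated_labels,
               tr$annotation$annotated_labels)
  expect_error(sparsify_annotation(tr, 0), "keep_fraction")

  kept <- vapply(1:300, function(s)
    length(sparsify_annotation(tr, 0.5, seed = s)$annotated_labels), numeric(1))
  expect_lt(abs(mean(kept) / 2 - 0.5), 0.1)   # 2 labels per phantom
  expect_true(all(vapply(1:50, function(s)
    all(sparsify_annotation(tr, 0.5, seed = s)$annotated_labels %in%
          tr$annotation$annotated_labels), logical(1))))
})
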