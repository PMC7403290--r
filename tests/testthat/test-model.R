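test_that("the full-scale config reproduces the declared receptive field exactly", {
  cfg <- preset_network_config("full", "semantic", n_labels = 99)
  rf <- receptive_field(cfg)
  expect_equal(as.integer(rf), c(136L, 136L, 72L))
  mm <- receptive_field_mm(rf, cfg$spacing)
  expect_equal(mm, c(184.96, 184.96, 216))
  expect_equal(mm[3], 216)   # z extent in mm, exact
})

test_that("receptive_field_mm is an elementwise product", {
  expect_equal(receptive_field_mm(c(1, 1, 1), c(1, 1, 1)), c(1, 1, 1))
  expect_equal(receptive_field_mm(c(10, 20, 30), c(2, 2, 2)), c(20, 40, 60))
  expect_error(receptive_field_mm(c(0, 1, 1), c(1, 1, 1)), "positive")
})

test_that("layer-stack receptive field matches a numerical influence probe", {
  # all-linear activations so influence cannot vanish through dead ReLUs
  layers <- list(conv_layer(c(3, 3, 3), 2L, "linear"),
                 pool_layer(c(2, 2, 2)),
                 conv_layer(c(3, 3, 3), 2L, "linear"))
  cfg <- network_config("semantic", n_labels = 1, layers = layers,
                        patch_size = c(8, 8, 8))
  rf <- receptive_field(cfg)
  expect_equal(as.integer(rf), c(8L, 8L, 8L))
  set.seed(101)
  net <- build_network(cfg)
  x <- array(stats::rnorm(8^3), c(8, 8, 8))
  base <- orgseg:::.net_forward_raw(net, x)$head
  expect_equal(dim(base)[1:3], c(1L, 1L, 1L))
  # every voxel of an rf-sized input influences the single output voxel
  changed <- vapply(1:8, function(i) {
    x2 <- x; x2[i, i, i] <- x2[i, i, i] + 1
    any(orgseg:::.net_forward_raw(net, x2)$head != base)
  }, logical(1))
  expect_true(all(changed))
})

test_that("network heads have the documented channel counts", {
  sem <- build_network(preset_network_config("desk", "semantic", n_labels = 2))
  set.seed(1)
  x <- array(stats::rnorm(12^3), c(12, 12, 12))
  out <- network_apply(sem, x)
  expect_equal(dim(out$probs)[4], 3L)        # 2 labels + background
  expect_null(out$linear)

  ins <- build_network(preset_network_config("desk", "instance"))
  out2 <- network_apply(ins, x)
  expect_equal(dim(out2$probs)[4], 3L)       # background / vertebra / rib
  expect_equal(dim(out2$linear)[4], 3L)      # centre regression -> 6 outputs
  # SoftMax channels sum to 1 at every voxel
  s <- apply(out2$probs, 1:3, sum)
  expect_true(all(abs(s - 1) < 1e-5))
})

test_that("patches smaller than the receptive field are rejected", {
  cfg <- network_config("semantic", n_labels = 1,
                        layers = list(conv_layer(c(5, 5, 5), 4L)),
                        patch_size = c(4, 4, 4))
  expect_error(build_network(cfg), "receptive field")
})

test_that("masked loss matches its closed forms and a brute-force subset mean", {
  d <- c(4, 4, 2); C <- 3
  tgt <- array(sample(1:C, prod(d), replace = TRUE), d)
  perfect <- array(0, c(d, C))
  n <- prod(d)
  perfect[seq_len(n) + (as.integer(tgt) - 1L) * n] <- 1
  expect_lt(masked_loss(perfect, tgt), 1e-10)

  unif <- array(1 / C, c(d, C))
  expect_equal(masked_loss(unif, tgt), log(C), tolerance = 1e-12)

  set.seed(5)
  raw <- array(stats::runif(prod(d) * C), c(d, C))
  probs <- raw / array(rep(apply(raw, 1:3, sum), C), c(d, C))
  mask <- array(rep(c(1, 0), length.out = prod(d)), d)
  got <- masked_loss(probs, tgt, mask)
  bf <- {
    tot <- 0; cnt <- 0
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      if (mask[i, j, k] == 1) {
        tot <- tot - log(probs[i, j, k, tgt[i, j, k]]); cnt <- cnt + 1
      }
    tot / cnt
  }
  expect_equal(got, bf, tolerance = 1e-12)

  expect_warning(z <- masked_loss(probs, tgt, array(0, d)), "all-zero")
  expect_equal(z, 0)
})

test_that("tiled inference is exactly independent of the tiling plan", {
  set.seed(42)
  net <- build_network(preset_network_config("desk", "semantic", n_labels = 2))
  g <- image_grid(c(20, 18, 16), c(2, 2, 3))
  vol <- volume(array(stats::rnorm(prod(g$shape), 0, 400), g$shape), g)

  single <- predict_volume(net, vol, tile = c(64, 64, 64))  # one tile
  plan_a <- predict_volume(net, vol, tile = c(7, 9, 5))
  plan_b <- predict_volume(net, vol, tile = c(11, 6, 16))
  expect_identical(single$probs, plan_a$probs)
  expect_identical(single$probs, plan_b$probs)

  # SoftMax channels sum to one everywhere
  s <- apply(single$probs, 1:3, sum)
  expect_true(all(abs(s - 1) < 1e-5))
})

test_that("constant input yields a spatially constant output field", {
  set.seed(7)
  net <- build_network(preset_network_config("desk", "semantic", n_labels = 1))
  g <- image_grid(c(14, 14, 14), c(2, 2, 3))
  vol <- volume(array(100, g$shape), g)
  out <- predict_volume(net, vol)
  for (c in seq_len(dim(out$probs)[4])) {
    ch <- out$probs[, , , c]
    expect_lt(max(ch) - min(ch), 1e-12)
  }
})

test_that("training is seed-deterministic and a zero learning rate is a null update", {
  data <- list(tiny_phantom(seed = 1, noise_sd = 10),
               tiny_phantom(seed = 2, noise_sd = 10))
  cfg <- network_config("semantic", n_labels = 2, label_values = c(1L, 2L),
                        layers = list(conv_layer(c(3, 3, 3), 4L)),
                        patch_size = c(9, 9, 9))
  set.seed(11); net <- build_network(cfg)
  tc <- training_config(epochs = 1L, iters_per_epoch = 3L, batch_size = 2L,
                        patch_size = c(9, 9, 9), seed = 99)
  r1 <- train_network(net, data, tc)
  r2 <- train_network(net, data, tc)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net$layers, r2$net$layers)
  expect_identical(sort(c(r1$split$train, r1$split$validation)), 1:2)

  tc0 <- training_config(epochs = 1L, iters_per_epoch = 2L, batch_size = 1L,
                         lr = 0, patch_size = c(9, 9, 9), seed = 99)
  r0 <- train_network(net, data, tc0)
  expect_identical(r0$net$layers, net$layers)
})

test_that("network checkpoints round-trip through save/load", {
  set.seed(3)
  net <- build_network(preset_network_config("desk", "instance"))
  d <- file.path(tempdir(), "ckpt")
  unlink(d, recursive = TRUE)
  save_network(net, d)
  back <- load_network(d)
  expect_identical(back$layers, net$layers)
  side <- jsonlite::read_json(file.path(d, "config.json"))
  expect_equal(side$kind, "instance")
  expect_equal(unlist(side$receptive_field), c(7, 7, 7))
})
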