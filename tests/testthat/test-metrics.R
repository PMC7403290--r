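make_map <- function(arr, grid = tiny_grid(dim(arr))) label_map(arr, grid)

test_that("confusion counts match exhaustive enumeration on toy maps", {
  set.seed(21)
  for (rep in 1:5) {
    g <- tiny_grid(c(3, 3, 1))
    p <- make_map(array(sample(0:2, 9, replace = TRUE), c(3, 3, 1)), g)
    t <- make_map(array(sample(0:2, 9, replace = TRUE), c(3, 3, 1)), g)
    got <- confusion_counts(p, t, labels = 1:2)
    expect_equal(got, bf_confusion(p$labels, t$labels, 1:2))
  }
})

test_that("identity and disjoint predictions give the expected counts", {
  t <- make_map(array(c(rep(1L, 10), rep(2L, 6), rep(0L, 48)), c(4, 4, 4)))
  idt <- confusion_counts(t, t)
  expect_true(all(idt$fp == 0) && all(idt$fn == 0))

  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[3:4, 4, 4] <- 1L
  dj <- confusion_counts(make_map(a), make_map(b))
  expect_equal(dj$tp, 0L)
})

test_that("dice/recall/precision follow their closed forms and conventions", {
  m <- dice_recall_precision(c(1, 1, 1))   # |A| = |B| = 2, overlap 1
  expect_equal(m$dice, 0.5)
  idm <- dice_recall_precision(c(10, 0, 0))
  expect_equal(unlist(idm[c("dice", "recall", "precision")], use.names = FALSE),
               c(1, 1, 1))
  z <- dice_recall_precision(c(0, 3, 0))
  expect_equal(z$dice, 0)
  expect_equal(z$precision, 0)
  # empty-vs-empty convention: 1 by default, NA on request
  e <- dice_recall_precision(c(0, 0, 0))
  expect_equal(unlist(e[c("dice", "recall", "precision")], use.names = FALSE),
               c(1, 1, 1))
  expect_true(is.na(dice_recall_precision(c(0, 0, 0), empty_value = NA)$dice))
  expect_error(dice_recall_precision(c(-1, 0, 0)), ">= 0")
})

test_that("dice is the harmonic mean of precision and recall on random count triples", {
  set.seed(33)
  for (i in 1:200) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    m <- dice_recall_precision(c(tp, fp, fn))
    hm <- if (m$precision + m$recall > 0)
      2 * m$precision * m$recall / (m$precision + m$recall) else 0
    expect_equal(m$dice, hm, tolerance = 1e-12)
    expect_lte(m$dice, 1)
  }
})

test_that("foreground metrics are label-blind and match brute force", {
  set.seed(4)
  g <- tiny_grid(c(5, 5, 2))
  p <- make_map(array(sample(0:3, 50, replace = TRUE), c(5, 5, 2)), g)
  t <- make_map(array(sample(0:3, 50, replace = TRUE), c(5, 5, 2)), g)
  fm <- foreground_metrics(p, t)
  pb <- p$labels > 0; tb <- t$labels > 0
  expect_equal(fm$tp, sum(pb & tb))
  expect_equal(fm$fp, sum(pb & !tb))
  expect_equal(fm$fn, sum(!pb & tb))

  expect_equal(unlist(foreground_metrics(t, t)[c("dice", "recall", "precision")],
                      use.names = FALSE), c(1, 1, 1))

  # renaming a label leaves foreground metrics unchanged
  renamed <- t$labels; renamed[renamed == 2L] <- 9L
  expect_equal(foreground_metrics(p, make_map(renamed, g)), fm)
})

test_that("group aggregation averages per-label metrics and handles dispersion", {
  tab <- data.frame(label = 1:3, tp = c(8, 9, 50), fp = c(2, 1, 0),
                    fn = c(2, 1, 0))
  tab <- dice_recall_precision(tab)
  tab$group <- c("bone", "bone", "soft_tissue")
  agg <- aggregate_metrics(tab)
  expect_equal(agg$dice[agg$group == "bone"],
               mean(tab$dice[1:2]))
  expect_equal(agg$n_labels[agg$group == "all"], 3L)

  one <- aggregate_metrics(tab[3, ])
  expect_equal(one$dice[one$group == "soft_tissue"], tab$dice[3])

  pooled <- aggregate_metrics(tab, mode = "pooled")
  expect_equal(pooled$dice[pooled$group == "bone"],
               2 * 17 / (2 * 17 + 3 + 3))

  same <- dispersion_across_cases(list(tab, tab, tab))
  expect_true(all(same$dice_sd == 0))
  expect_error(aggregate_metrics(tab[0, ]), "empty")
})

test_that("two organs at 0.8 and 0.9 average to 0.85", {
  tab <- data.frame(label = 1:2, tp = c(4, 9), fp = c(1, 1), fn = c(1, 1),
                    dice = c(0.8, 0.9), recall = c(0.8, 0.9),
                    precision = c(0.8, 0.9), group = c("bone", "bone"))
  agg <- aggregate_metrics(tab)
  expect_equal(agg$dice[agg$group == "bone"], 0.85)
})

test_that("inter-observer metrics are symmetric in dice, swap recall/precision", {
  set.seed(12)
  g <- tiny_grid(c(6, 6, 3))
  r1 <- make_map(array(sample(0:2, 108, replace = TRUE), c(6, 6, 3)), g)
  r2 <- make_map(array(sample(0:2, 108, replace = TRUE), c(6, 6, 3)), g)
  io12 <- interobserver(r1, r2)
  io21 <- interobserver(r2, r1)
  expect_equal(io12$per_label$dice, io21$per_label$dice)
  expect_equal(io12$per_label$recall, io21$per_label$precision)
  expect_equal(io12$foreground$dice, io21$foreground$dice)

  self <- interobserver(r1, r1)
  expect_true(all(self$per_label$dice == 1))
  expect_equal(self$foreground$dice, 1)
})

test_that("excluding an unannotated label leaves other labels' metrics unchanged", {
  set.seed(40)
  g <- tiny_grid(c(6, 6, 4))
  t <- array(0L, c(6, 6, 4)); t[1:3, 1:3, 1] <- 1L; t[4:6, 4:6, 2] <- 2L
  p <- t
  p[1, 1, 1] <- 0L          # an error on label 1
  tm <- make_map(t, g); pm <- make_map(p, g)
  full <- compute_metrics(pm, tm)
  sparse <- compute_metrics(pm, tm, annotation = annotation_mask(1L))
  expect_equal(sparse$dice[sparse$label == 1L], full$dice[full$label == 1L])
  expect_false(2L %in% sparse$label)
})
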