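# Compare two voxel partitions up to instance relabelling.
same_partition <- function(a, b) {
  av <- as.vector(a); bv <- as.vector(b)
  if (!identical(av > 0, bv > 0)) return(FALSE)
  fg <- av > 0
  key <- paste(av[fg], bv[fg])
  length(unique(key)) == length(unique(av[fg])) &&
    length(unique(key)) == length(unique(bv[fg]))
}

test_that("clustering exact centre fields recovers the true instances", {
  for (seed in 1:8) {
    n_vert <- 3 + (seed %% 6)
    tr <- desk_spine_phantom(seed, n_vertebrae = n_vert)
    field <- instance_field_from_truth(tr)
    pitch <- spine_pitch_mm(tr$spec$spine)
    cl <- cluster_instances(field, cluster_params(linkage_mm = pitch / 2))
    expect_equal(nrow(cl$instances), n_vert)
    expect_true(same_partition(cl$instance_map, tr$instance_id))
  }
})

test_that("clustering tolerates centre jitter well below the linkage threshold", {
  ok <- 0L
  for (seed in 1:10) {
    n_vert <- 3 + (seed %% 6)
    tr <- desk_spine_phantom(100 + seed, n_vertebrae = n_vert)
    field <- instance_field_from_truth(tr)
    gap <- tr$spec$spine$gap_mm
    set.seed(seed)
    jit <- array(stats::rnorm(length(field$centres), 0, 0.1 * gap),
                 dim(field$centres))
    jit[is.na(field$centres)] <- NA
    field$centres <- field$centres + jit
    pitch <- spine_pitch_mm(tr$spec$spine)
    cl <- cluster_instances(field, cluster_params(linkage_mm = pitch / 2))
    if (nrow(cl$instances) == n_vert &&
        same_partition(cl$instance_map, tr$instance_id)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("empty foreground clusters to zero instances", {
  g <- image_grid(c(8, 8, 8), c(2, 2, 3))
  probs <- array(0, c(8, 8, 8, 3)); probs[, , , 1] <- 1
  field <- structure(list(probs = probs, centres = array(NA_real_, c(8, 8, 8, 3)),
                          grid = g), class = "instance_field")
  cl <- cluster_instances(field)
  expect_equal(nrow(cl$instances), 0L)
  expect_true(all(cl$instance_map == 0L))
})

test_that("vertebra numbering runs cranio-caudally and matches the phantom truth", {
  tr <- desk_spine_phantom(seed = 5, n_vertebrae = 5)
  cl <- cluster_instances(instance_field_from_truth(tr),
                          cluster_params(spine_pitch_mm(tr$spec$spine) / 2))
  lab <- assign_indices(cl, default_registry(), start = "lumbar")
  expect_identical(lab$labels, tr$labels$labels)
  reg <- default_registry()
  got <- sort(setdiff(unique(as.vector(lab$labels)), 0L))
  expect_equal(reg$name[match(got, reg$index)],
               paste("Lumbar vertebrae", 1:5))

  # singleton: one instance takes the first slot
  tr1 <- desk_spine_phantom(seed = 6, n_vertebrae = 1)
  cl1 <- cluster_instances(instance_field_from_truth(tr1),
                           cluster_params(12))
  lab1 <- assign_indices(cl1, reg, start = "lumbar")
  expect_equal(setdiff(unique(as.vector(lab1$labels)), 0L),
               reg$index[reg$name == "Lumbar vertebrae 1"])
})

test_that("vertebra numbering is equivariant to global z-translation", {
  tr <- desk_spine_phantom(seed = 9, n_vertebrae = 4)
  field <- instance_field_from_truth(tr)
  cl <- cluster_instances(field, cluster_params(12))
  lab <- assign_indices(cl, start = "thoracic")

  g2 <- image_grid(tr$ct$grid$shape, tr$ct$grid$spacing,
                   origin = tr$ct$grid$origin + c(0, 0, 250))
  field2 <- field; field2$grid <- g2
  field2$centres[, , , 3] <- field2$centres[, , , 3] + 250
  cl2 <- cluster_instances(field2, cluster_params(12))
  lab2 <- assign_indices(cl2, start = "thoracic")
  expect_identical(lab$labels, lab2$labels)
})

test_that("ribs get the nearest vertebra level and the correct side", {
  tr <- desk_spine_phantom(seed = 12, n_vertebrae = 3,
                           rib_pairs_range = c(1L, 1L))
  expect_true(any(tr$instance_centres$class == "rib"))
  cl <- cluster_instances(instance_field_from_truth(tr),
                          cluster_params(spine_pitch_mm(tr$spec$spine) / 2))
  lab <- assign_indices(cl, start = "thoracic")
  reg <- default_registry()
  mid_x <- mean(tr$instance_centres$cx[tr$instance_centres$class == "vertebra"])
  ribs <- cl$instances[cl$instances$class == "rib", ]
  for (i in seq_len(nrow(ribs))) {
    k <- unique(lab$labels[cl$instance_map == ribs$id[i]])
    nm <- reg$name[match(k, reg$index)]
    if (ribs$cx[i] > mid_x) expect_match(nm, "^Rib left")
    else expect_match(nm, "^Rib right")
  }
})

test_that("instance overflow beyond the registry slots warns and truncates", {
  tr <- desk_spine_phantom(seed = 20, n_vertebrae = 7,
                           )
  cl <- cluster_instances(instance_field_from_truth(tr),
                          cluster_params(spine_pitch_mm(tr$spec$spine) / 2))
  expect_warning(lab <- assign_indices(cl, start = "lumbar"), "exceed")
  reg <- default_registry()
  got <- setdiff(unique(as.vector(lab$labels)), 0L)
  expect_equal(length(got), 5L)   # only the 5 lumbar slots are filled
})

test_that("largest component matches the igraph oracle and its tie rule", {
  for (seed in 1:20) {
    m <- random_mask(seed, c(10, 10, 6), p = 0.2)
    got <- largest_component(m, 26)
    bf <- bf_components(m, 26)
    if (bf$n == 0L) { expect_false(any(got)); next }
    sizes <- tabulate(bf$membership)
    expect_equal(sum(got), max(sizes))
    # the kept voxels form exactly one oracle component
    kept_members <- unique(bf$membership[match(which(got), bf$vox)])
    expect_equal(length(kept_members), 1L)
    # idempotence
    expect_identical(largest_component(got, 26), got)
  }
  # deterministic tie-break: equal sizes -> earliest (z, y, x) seed wins
  m <- array(FALSE, c(7, 3, 3))
  m[1:2, 1, 1] <- TRUE      # earliest in scan order
  m[5:6, 2, 2] <- TRUE
  got <- largest_component(m, 26)
  expect_identical(which(got), which(array(seq_len(63), c(7, 3, 3)) %in% c(1, 2)))
})

test_that("6- vs 26-connectivity distinguish diagonal touching", {
  m <- array(FALSE, c(4, 4, 1))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE
  expect_equal(sum(largest_component(m, 26)), 2L)
  expect_equal(sum(largest_component(m, 6)), 1L)
})

test_that("hole filling matches a flood-fill oracle on shells and random masks", {
  # hollow cube shell -> solid cube
  shell <- array(FALSE, c(8, 8, 8))
  shell[2:7, 2:7, 2:7] <- TRUE
  shell[3:6, 3:6, 3:6] <- FALSE
  filled <- fill_holes(shell)
  expect_true(all(filled[2:7, 2:7, 2:7]))
  expect_false(any(filled[1, , ]))

  # solid blob unchanged; empty unchanged
  solid <- array(FALSE, c(6, 6, 6)); solid[2:5, 2:5, 2:5] <- TRUE
  expect_identical(fill_holes(solid), solid)
  expect_identical(fill_holes(array(FALSE, c(4, 4, 4))), array(FALSE, c(4, 4, 4)))

  for (seed in 31:40) {
    m <- random_mask(seed, c(8, 8, 6), p = 0.35)
    expect_identical(fill_holes(m), bf_fill_holes(m))
  }
})

test_that("postprocessing yields a single component without holes, idempotently", {
  for (seed in 51:56) {
    m <- random_mask(seed, c(10, 10, 8), p = 0.3)
    if (!any(m)) next
    pp <- postprocess_mask(m)
    lab <- orgseg:::cpp_cc3d(array(as.integer(pp), dim(pp)), dim(pp), 26L)
    expect_equal(attr(lab, "n_components"), 1L)
    expect_identical(fill_holes(pp), pp)
    expect_identical(postprocess_mask(pp), pp)
  }
})

test_that("fusion without instances reduces to semantic argmax plus morphology", {
  set.seed(60)
  g <- image_grid(c(10, 10, 6), c(2, 2, 3))
  probs <- array(stats::runif(prod(g$shape) * 3), c(g$shape, 3))
  probs <- probs / array(rep(apply(probs, 1:3, sum), 3), dim(probs))
  sem <- structure(list(probs = probs, label_values = c(4L, 9L), grid = g),
                   class = "semantic_field")
  f1 <- fuse(sem, NULL, morphology = FALSE)
  expect_identical(f1$labels, argmax_labels(sem)$labels)

  # argmax ties break toward the lower label index
  tie <- probs
  tie[1, 1, 1, ] <- c(0.4, 0.4, 0.2)
  semt <- structure(list(probs = tie, label_values = c(4L, 9L), grid = g),
                    class = "semantic_field")
  expect_equal(argmax_labels(semt)$labels[1, 1, 1], 0L)  # background channel wins tie
  tie[1, 1, 1, ] <- c(0.1, 0.45, 0.45)
  semt$probs <- tie
  expect_equal(argmax_labels(semt)$labels[1, 1, 1], 4L)  # lower label wins
})

test_that("fusing spine instances with semantic organs keeps all true labels", {
  tr <- desk_spine_phantom(seed = 70, n_vertebrae = 5)
  # a perfect semantic field that claims everything as background
  d <- tr$ct$grid$shape
  probs <- array(0, c(d, 2)); probs[, , , 1] <- 1
  sem <- structure(list(probs = probs, label_values = 1L, grid = tr$ct$grid),
                   class = "semantic_field")
  cl <- cluster_instances(instance_field_from_truth(tr),
                          cluster_params(spine_pitch_mm(tr$spec$spine) / 2))
  inst <- assign_indices(cl, start = "lumbar")
  fused <- fuse(sem, inst, default_registry())
  expect_setequal(setdiff(unique(as.vector(fused$labels)), 0L),
                  setdiff(unique(as.vector(tr$labels$labels)), 0L))
})
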