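# The package's desk-scale learning and recovery experiments: seeded,
# self-contained procedures used by the test suite and the reproduction
# script. Problem sizes (20 semantic phantoms of 64^3 voxels, 10 spine
# phantoms, ~2400 / ~800 optimisation steps) are chosen so each experiment
# trains in a few minutes on one CPU core while leaving a comfortable
# margin to its accuracy target.

#' Desk-scale semantic segmentation experiment
#'
#' Trains the reduced semantic network on seeded three-organ phantoms
#' (80/20 study-level split) and evaluates per-label Dice on the held-out
#' studies. Training uses foreground-biased patches and class-balanced
#' cross-entropy: with three organs spanning contrasts from 0.94 to 0.125
#' on the normalised scale, plain cross-entropy under class imbalance
#' leaves the lowest-contrast organ (lung vs air) below the argmax
#' threshold within a CPU-scale step budget.
#'
#' @param seed base seed; phantom generation, initialisation and training
#'   derive their seeds from it.
#' @param n_phantoms number of phantom studies.
#' @param epochs,iters_per_epoch,batch_size,lr,patch training schedule.
#' @return A list with `trained` (the [train_network()] result), `dice`
#'   (matrix: label x validation study), `min_dice`, `mean_dice` and
#'   `labels`.
#' @export
desk_semantic_experiment <- function(seed = 1L, n_phantoms = 20L,
                                     epochs = 60L, iters_per_epoch = 40L,
                                     batch_size = 3L, lr = 5e-3,
                                     patch = c(14, 14, 14)) {
  data <- desk_semantic_set(n_phantoms, seed_base = seed * 1000L)
  labs <- desk_semantic_labels()
  cfg <- preset_network_config("desk", "semantic", n_labels = length(labs),
                               label_values = labs)
  set.seed(seed)
  net <- build_network(cfg)
  tc <- training_config(epochs = epochs, iters_per_epoch = iters_per_epoch,
                        batch_size = batch_size, lr = lr, patch_size = patch,
                        fg_bias = 1, class_balance = TRUE, seed = seed)
  trained <- train_network(net, data, tc)
  dice <- vapply(trained$split$validation, function(i) {
    ph <- data[[i]]
    pred <- argmax_labels(predict_volume(trained, ph$ct, tile = c(32, 32, 32)))
    compute_metrics(pred, ph$labels, labels = labs)$dice
  }, numeric(length(labs)))
  rownames(dice) <- as.character(labs)
  list(trained = trained, dice = dice, min_dice = min(dice),
       mean_dice = mean(dice), labels = labs)
}

#' Desk-scale instance network experiment
#'
#' Trains the instance network (background/vertebra/rib classification plus
#' per-voxel centre-offset regression) on seeded spine phantoms and
#' reports, on the held-out studies, the mean Euclidean error of the
#' predicted instance centres over vertebra voxels, the vertebra-voxel
#' classification accuracy, and the instance counts recovered by
#' centre clustering.
#'
#' @inheritParams desk_semantic_experiment
#' @return A list with `trained`, `per_phantom` (data frame: study,
#'   n_true, n_clustered, mean_err_mm, class_acc), `mean_centre_err_mm`,
#'   `count_accuracy` and `gap_mm` / `pitch_mm` of the spine population.
#' @export
desk_instance_experiment <- function(seed = 1L, n_phantoms = 10L,
                                     epochs = 20L, iters_per_epoch = 40L,
                                     batch_size = 3L, lr = 5e-3,
                                     patch = c(14, 14, 14)) {
  data <- desk_spine_set(n_phantoms, seed_base = seed * 2000L)
  cfg <- preset_network_config("desk", "instance")
  set.seed(seed)
  net <- build_network(cfg)
  tc <- training_config(epochs = epochs, iters_per_epoch = iters_per_epoch,
                        batch_size = batch_size, lr = lr, patch_size = patch,
                        fg_bias = 0.9, class_balance = TRUE, seed = seed)
  trained <- train_network(net, data, tc)
  rows <- lapply(trained$split$validation, function(i) {
    ph <- data[[i]]
    fld <- predict_volume(trained, ph$ct, tile = ph$ct$grid$shape)
    vm <- ph$instance_id > 0
    ic <- ph$instance_centres
    row <- match(ph$instance_id[vm], ic$id)
    truec <- cbind(ic$cx[row], ic$cy[row], ic$cz[row])
    predc <- cbind(fld$centres[, , , 1][vm], fld$centres[, , , 2][vm],
                   fld$centres[, , , 3][vm])
    err <- sqrt(rowSums((predc - truec)^2))
    cls <- array(cpp_argmax4(as.numeric(fld$probs), dim(fld$probs)), dim(vm))
    cl <- cluster_instances(fld, cluster_params(spine_pitch_mm(ph$spec$spine) / 2))
    data.frame(study = i, n_true = nrow(ic),
               n_clustered = sum(cl$instances$class == "vertebra"),
               mean_err_mm = mean(err),
               class_acc = mean(cls[vm] == 2L))
  })
  per <- do.call(rbind, rows)
  sp <- data[[1]]$spec$spine
  list(trained = trained, per_phantom = per,
       mean_centre_err_mm = mean(per$mean_err_mm),
       count_accuracy = mean(per$n_clustered == per$n_true),
       gap_mm = sp$gap_mm, pitch_mm = spine_pitch_mm(sp))
}

#' Instance recovery from exact and jittered centre fields
#'
#' The clustering-only experiment: seeded spine phantoms (vertebra counts
#' cycling 3..8) are converted to exact instance fields; optionally every
#' per-voxel centre is jittered with isotropic Gaussian noise of standard
#' deviation `jitter_frac` times the clear inter-vertebral gap. Clustering
#' at half the vertebral pitch must recover the exact instance count and
#' voxel partition.
#'
#' @param n_phantoms number of phantoms.
#' @param jitter_frac centre jitter sd as a fraction of the gap (0 = exact).
#' @param seed base seed.
#' @return A list with `recovered` (logical per phantom), `rate`
#'   (fraction with exact count and partition) and `n_phantoms`.
#' @export
instance_recovery_experiment <- function(n_phantoms = 50L, jitter_frac = 0,
                                         seed = 1L) {
  counts <- 3:8
  recovered <- logical(n_phantoms)
  for (i in seq_len(n_phantoms)) {
    nv <- counts[((i - 1L) %% length(counts)) + 1L]
    tr <- desk_spine_phantom(seed * 3000L + i, n_vertebrae = nv)
    fld <- instance_field_from_truth(tr)
    if (jitter_frac > 0) {
      set.seed(seed * 3000L + i)
      jit <- array(stats::rnorm(length(fld$centres), 0,
                                jitter_frac * tr$spec$spine$gap_mm),
                   dim(fld$centres))
      jit[is.na(fld$centres)] <- NA
      fld$centres <- fld$centres + jit
    }
    cl <- cluster_instances(fld, cluster_params(spine_pitch_mm(tr$spec$spine) / 2))
    recovered[i] <- nrow(cl$instances) == nv &&
      .same_partition(cl$instance_map, tr$instance_id)
  }
  list(recovered = recovered, rate = mean(recovered), n_phantoms = n_phantoms)
}

# Two voxel partitions are equal up to instance relabelling.
.same_partition <- function(a, b) {
  av <- as.vector(a); bv <- as.vector(b)
  if (!identical(av > 0, bv > 0)) return(FALSE)
  fg <- av > 0
  key <- paste(av[fg], bv[fg])
  length(unique(key)) == length(unique(av[fg])) &&
    length(unique(key)) == length(unique(bv[fg]))
}
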