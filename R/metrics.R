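#' Per-label confusion counts between predicted and reference label maps
#'
#' Counts overlapping voxels per label: TP (both maps carry the label), FP
#' (prediction only), FN (reference only). Voxels whose reference label is
#' not annotated in the study are excluded from all counts, and unannotated
#' labels are not reported, mirroring how partially annotated studies are
#' handled in training.
#'
#' @param pred,truth [label_map()]s on the same grid.
#' @param annotation an [annotation_mask()] or `NULL` (fully annotated).
#' @param labels integer vector of labels to report; defaults to all labels
#'   present in either map (intersected with the annotated set).
#' @return Data frame with columns `label`, `tp`, `fp`, `fn` (exact integer
#'   counts).
#' @export
confusion_counts <- function(pred, truth, annotation = NULL, labels = NULL) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  if (!identical(pred$grid$shape, truth$grid$shape))
    stop("prediction and reference grids do not match")
  pv <- as.vector(pred$labels)
  tv <- as.vector(truth$labels)
  if (!is.null(annotation)) {
    keep <- tv %in% c(0L, annotation$annotated_labels)
    pv <- pv[keep]; tv <- tv[keep]
  }
  if (is.null(labels)) {
    labels <- sort(setdiff(union(unique(pv), unique(tv)), 0L))
    if (!is.null(annotation))
      labels <- intersect(labels, annotation$annotated_labels)
  }
  tp <- fp <- fn <- integer(length(labels))
  for (i in seq_along(labels)) {
    k <- labels[i]
    p <- pv == k; t <- tv == k
    tp[i] <- sum(p & t); fp[i] <- sum(p & !t); fn[i] <- sum(!p & t)
  }
  data.frame(label = labels, tp = tp, fp = fp, fn = fn)
}

#' Dice, recall and precision from confusion counts
#'
#' `dice = 2TP / (2TP + FP + FN)`, `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`. Dice is the harmonic mean of precision and
#' recall whenever both are defined. When both masks are empty
#' (TP = FP = FN = 0) all three metrics default to 1 (agreement on
#' absence); set `empty_value = NA` to mark them undefined instead.
#'
#' @param counts data frame with columns `tp`, `fp`, `fn` (or a single
#'   numeric vector `c(tp, fp, fn)`).
#' @param empty_value value reported for empty-vs-empty comparisons.
#' @return Data frame with columns `dice`, `recall`, `precision` (joined to
#'   the input columns).
#' @export
dice_recall_precision <- function(counts, empty_value = 1) {
  if (is.numeric(counts) && length(counts) == 3L)
    counts <- data.frame(tp = counts[1], fp = counts[2], fn = counts[3])
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0")
  dice <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), empty_value)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn),
                   ifelse(fp > 0, 0, empty_value))
  precision <- ifelse(tp + fp > 0, tp / (tp + fp),
                      ifelse(fn > 0, 0, empty_value))
  cbind(counts, data.frame(dice = dice, recall = recall, precision = precision))
}

#' Per-label metrics table for a segmentation pair
#'
#' Convenience wrapper: confusion counts followed by
#' [dice_recall_precision()], with registry names and groups attached.
#'
#' @inheritParams confusion_counts
#' @param registry optional [label_registry] supplying names and groups.
#' @param empty_value see [dice_recall_precision()].
#' @return A data frame of class `metrics_table`.
#' @export
compute_metrics <- function(pred, truth, annotation = NULL, registry = NULL,
                            labels = NULL, empty_value = 1) {
  tab <- dice_recall_precision(confusion_counts(pred, truth, annotation, labels),
                               empty_value)
  if (!is.null(registry)) {
    row <- match(tab$label, registry$index)
    tab <- cbind(data.frame(name = registry$name[row],
                            group = registry$group[row]), tab)
  }
  class(tab) <- c("metrics_table", "data.frame")
  tab
}

#' Foreground (label-blind) agreement metrics
#'
#' Metrics computed on the binarised union of all labels against
#' background; invariant under any renaming of foreground labels.
#'
#' @param pred,truth [label_map()]s on the same grid.
#' @return One-row data frame with `dice`, `recall`, `precision` (and the
#'   underlying counts).
#' @export
foreground_metrics <- function(pred, truth) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  if (!identical(pred$grid$shape, truth$grid$shape))
    stop("prediction and reference grids do not match")
  p <- pred$labels > 0L; t <- truth$labels > 0L
  dice_recall_precision(c(sum(p & t), sum(p & !t), sum(!p & t)))
}

#' Aggregate a metrics table into group means
#'
#' Two aggregation modes are provided because a per-organ average and a
#' voxel-pooled metric answer different questions: `"per_label_mean"` takes
#' the unweighted mean of the per-label metrics within each group (the way
#' per-organ tables are usually averaged); `"pooled"` sums the confusion
#' counts within the group first and computes the metrics once on the
#' pooled counts (weighting organs by size).
#'
#' @param table a [compute_metrics()] result carrying a `group` column (or
#'   a `registry` argument to supply it).
#' @param registry optional [label_registry] to attach groups.
#' @param mode `"per_label_mean"` or `"pooled"`.
#' @return Data frame with one row per group plus an `"all"` row; columns
#'   `group`, `n_labels`, `dice`, `recall`, `precision`, and for the
#'   per-label mode `dice_sd` (dispersion across labels).
#' @export
aggregate_metrics <- function(table, registry = NULL,
                              mode = c("per_label_mean", "pooled")) {
  mode <- match.arg(mode)
  if (!nrow(table)) stop("empty metrics table")
  if (is.null(table$group)) {
    if (is.null(registry)) stop("need a group column or a registry")
    table$group <- registry$group[match(table$label, registry$index)]
  }
  groups <- c(split(table, table$group), list(all = table))
  rows <- lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    if (mode == "per_label_mean") {
      data.frame(group = gn, n_labels = nrow(g), dice = mean(g$dice),
                 recall = mean(g$recall), precision = mean(g$precision),
                 dice_sd = stats::sd(g$dice))
    } else {
      m <- dice_recall_precision(c(sum(g$tp), sum(g$fp), sum(g$fn)))
      data.frame(group = gn, n_labels = nrow(g), dice = m$dice,
                 recall = m$recall, precision = m$precision,
                 dice_sd = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Per-label dispersion across cases
#'
#' Given one metrics table per case, reports the mean and standard
#' deviation of each label's Dice across cases.
#'
#' @param tables list of [compute_metrics()] results with matching labels.
#' @return Data frame with `label`, `dice_mean`, `dice_sd`, `n_cases`.
#' @export
dispersion_across_cases <- function(tables) {
  labs <- sort(unique(unlist(lapply(tables, `[[`, "label"))))
  rows <- lapply(labs, function(k) {
    v <- unlist(lapply(tables, function(t) t$dice[t$label == k]))
    data.frame(label = k, dice_mean = mean(v), dice_sd = stats::sd(v),
               n_cases = length(v))
  })
  do.call(rbind, rows)
}

#' Inter-observer agreement between two readers
#'
#' Treats reader 2 as the reference: Dice is symmetric under argument
#' exchange while recall and precision swap.
#'
#' @param reader1,reader2 [label_map()]s of the same study by two readers.
#' @param registry optional [label_registry].
#' @return A list with `per_label` (a `metrics_table`) and `foreground`
#'   (label-blind metrics row).
#' @export
interobserver <- function(reader1, reader2, registry = NULL) {
  list(per_label = compute_metrics(reader1, reader2, registry = registry),
       foreground = foreground_metrics(reader1, reader2))
}
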