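#' Fully convolutional network configuration
#'
#' Both segmentation networks are fully convolutional stacks of valid (no
#' padding) 3D convolutions, average poolings and nearest-neighbour
#' upsamplings. The semantic network ends in `n_labels + 1` SoftMax channels
#' (one per label plus background); the instance network ends in 3 SoftMax
#' channels (background, vertebra, rib) plus 3 linear channels that regress,
#' for every foreground voxel, the centre of the owning vertebra or rib.
#'
#' Layers are given as a list of `conv_layer()`, `pool_layer()` and
#' `upsample_layer()` entries; a 1x1x1 output convolution (the head) is
#' appended automatically. The declared receptive field of a config is
#' computable with [receptive_field()] and, for the full-scale preset,
#' equals (136, 136, 72) voxels -- approximately a cube in millimetres at the
#' (1.36, 1.36, 3) mm training spacing.
#'
#' @param kind `"semantic"` or `"instance"`.
#' @param n_labels number of foreground labels (semantic networks).
#' @param label_values integer registry indices mapped to the foreground
#'   channels, in channel order; defaults to `1:n_labels`.
#' @param layers list of layer descriptions (without the head).
#' @param patch_size training patch size in voxels; must not be smaller than
#'   the receptive field.
#' @param spacing training grid spacing in mm.
#' @param centre_scale mm scale dividing centre-offset regression targets so
#'   they are O(1) (instance networks).
#' @param centre_mode `"offset"` (predict centre minus voxel position; the
#'   translation-invariant default) or `"absolute"`.
#' @return An object of class `network_config`.
#' @export
network_config <- function(kind = c("semantic", "instance"), n_labels = NULL,
                           label_values = NULL, layers,
                           patch_size = c(24, 24, 24),
                           spacing = c(1.36, 1.36, 3),
                           centre_scale = 20, centre_mode = c("offset", "absolute")) {
  kind <- match.arg(kind)
  centre_mode <- match.arg(centre_mode)
  if (kind == "semantic") {
    if (is.null(n_labels)) stop("semantic networks need n_labels")
    if (is.null(label_values)) label_values <- seq_len(n_labels)
    if (length(label_values) != n_labels) stop("label_values length must equal n_labels")
    n_softmax <- n_labels + 1L
    n_linear <- 0L
  } else {
    n_softmax <- 3L
    n_linear <- 3L
    label_values <- NULL
  }
  for (l in layers)
    if (!l$type %in% c("conv", "pool", "upsample")) stop("unknown layer type: ", l$type)
  cfg <- structure(list(kind = kind, n_labels = n_labels,
                        label_values = as.integer(label_values),
                        layers = layers, n_softmax = n_softmax,
                        n_linear = n_linear, patch_size = as.integer(patch_size),
                        spacing = as.numeric(spacing),
                        centre_scale = centre_scale, centre_mode = centre_mode),
                   class = "network_config")
  cfg
}

#' @rdname network_config
#' @param kernel integer length-3 kernel size in voxels.
#' @param filters number of output channels.
#' @param activation `"relu"`, `"lrelu"` (leaky, slope 0.1) or `"linear"`.
#' @export
conv_layer <- function(kernel, filters, activation = "relu")
  list(type = "conv", kernel = as.integer(kernel), filters = as.integer(filters),
       activation = activation)

#' @rdname network_config
#' @param size integer length-3 pooling / upsampling factor.
#' @export
pool_layer <- function(size) list(type = "pool", size = as.integer(size))

#' @rdname network_config
#' @export
upsample_layer <- function(size) list(type = "upsample", size = as.integer(size))

#' Preset network configurations
#'
#' `"desk"` is a small single-resolution stack (receptive field 7^3 voxels)
#' trainable on a CPU in minutes, used by the package's phantom experiments.
#' `"full"` reproduces the declared constraints of the full-scale design:
#' four resolutions, pooling early in the stack, two kernel shapes
#' compensating the anisotropic (1.36, 1.36, 3) mm voxels, valid
#' convolutions, and a receptive field of exactly (136, 136, 72) voxels.
#'
#' @param preset `"desk"` or `"full"`.
#' @inheritParams network_config
#' @return A [network_config()].
#' @export
preset_network_config <- function(preset = c("desk", "full"),
                                  kind = c("semantic", "instance"),
                                  n_labels = NULL, label_values = NULL) {
  preset <- match.arg(preset)
  kind <- match.arg(kind)
  if (preset == "desk") {
    # leaky ReLU keeps gradients alive in flat strongly-negative CT regions
    # (air vs lung after clamp/scale), where plain ReLU units go dead
    layers <- list(conv_layer(c(3, 3, 3), 8L, "lrelu"),
                   conv_layer(c(3, 3, 3), 12L, "lrelu"),
                   conv_layer(c(3, 3, 3), 12L, "lrelu"))
    network_config(kind, n_labels, label_values, layers,
                   patch_size = c(24, 24, 24), spacing = c(2, 2, 3))
  } else {
    layers <- list(conv_layer(c(5, 5, 3), 16L),
                   conv_layer(c(5, 5, 3), 16L),
                   pool_layer(c(2, 2, 2)),
                   pool_layer(c(2, 2, 2)),
                   conv_layer(c(3, 3, 3), 32L),
                   conv_layer(c(3, 3, 3), 32L),
                   conv_layer(c(3, 3, 3), 32L),
                   pool_layer(c(2, 2, 1)),
                   conv_layer(c(5, 5, 3), 64L),
                   conv_layer(c(3, 3, 3), 64L),
                   conv_layer(c(3, 3, 3), 64L),
                   conv_layer(c(3, 3, 3), 64L),
                   conv_layer(c(3, 3, 3), 64L),
                   upsample_layer(c(2, 2, 1)),
                   upsample_layer(c(2, 2, 2)),
                   upsample_layer(c(2, 2, 2)))
    network_config(kind, n_labels, label_values, layers,
                   patch_size = c(136, 136, 72), spacing = c(1.36, 1.36, 3))
  }
}

#' Receptive field of a network configuration
#'
#' Walks the layer stack accumulating, per axis, the input extent seen by
#' one output voxel: each convolution adds `(kernel - 1) * jump`, pooling
#' multiplies the jump (and adds `(size - 1) * jump`), upsampling divides
#' the jump. The 1x1x1 head contributes nothing.
#'
#' @param config a [network_config()].
#' @return Integer length-3 receptive field in voxels, with attributes
#'   `jump` (final output stride per axis) and `unit_stride` (logical: the
#'   output lies on the input voxel lattice).
#' @examples
#' receptive_field(preset_network_config("full", "semantic", n_labels = 99))
#' @export
receptive_field <- function(config) {
  rf <- c(1, 1, 1); jump <- c(1, 1, 1)
  for (l in config$layers) {
    if (l$type == "conv") {
      rf <- rf + (l$kernel - 1) * jump
    } else if (l$type == "pool") {
      rf <- rf + (l$size - 1) * jump
      jump <- jump * l$size
    } else {
      jump <- jump / l$size
    }
  }
  structure(as.integer(rf), jump = jump,
            unit_stride = isTRUE(all(jump == 1)))
}

#' Receptive field extent in millimetres
#'
#' Elementwise product of the voxel receptive field and the grid spacing.
#' At the (1.36, 1.36, 3) mm training spacing the (136, 136, 72) voxel
#' field spans (184.96, 184.96, 216) mm -- approximately a cube.
#'
#' @param field_voxels integer length-3 receptive field in voxels.
#' @param spacing numeric length-3 spacing in mm.
#' @return Numeric length-3 extent in mm.
#' @export
receptive_field_mm <- function(field_voxels, spacing) {
  if (any(field_voxels <= 0) || any(spacing <= 0)) stop("inputs must be positive")
  as.numeric(field_voxels) * as.numeric(spacing)
}

#' Build (initialise) a network from a configuration
#'
#' Weights are He-initialised from the R session RNG (`set.seed()` first for
#' reproducibility). The returned network maps an input patch to an output
#' patch strictly smaller by the valid-convolution margins, reported in the
#' `margin` field.
#'
#' @param config a [network_config()].
#' @return An object of class `fcn_network` with fields `config`, `layers`
#'   (weights attached), `rf` and `margin` (voxels removed per side for
#'   unit-stride stacks, `NA` otherwise).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  rf <- receptive_field(config)
  if (any(config$patch_size < rf))
    stop(sprintf("patch size (%s) smaller than receptive field (%s)",
                 paste(config$patch_size, collapse = "x"),
                 paste(rf, collapse = "x")))
  layers <- config$layers
  layers[[length(layers) + 1L]] <-
    conv_layer(c(1, 1, 1), config$n_softmax + config$n_linear, "linear")
  cin <- 1L
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      fan_in <- prod(l$kernel) * cin
      sd <- sqrt(2 / fan_in)
      l$W <- array(stats::rnorm(prod(l$kernel) * cin * l$filters, 0, sd),
                   dim = c(l$kernel, cin, l$filters))
      l$b <- numeric(l$filters)
      cin <- l$filters
      layers[[i]] <- l
    }
  }
  margin <- if (isTRUE(attr(rf, "unit_stride")) && all((rf - 1L) %% 2L == 0L))
    (as.integer(rf) - 1L) %/% 2L else rep(NA_integer_, 3)
  structure(list(config = config, layers = layers, rf = as.integer(rf),
                 unit_stride = isTRUE(attr(rf, "unit_stride")),
                 margin = margin),
            class = "fcn_network")
}

#' @export
print.fcn_network <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    if (l$type == "conv") length(l$W) + length(l$b) else 0L, numeric(1)))
  cat(sprintf("fcn_network [%s]: %d layers, receptive field %s voxels, %d parameters\n",
              x$config$kind, length(x$layers),
              paste(x$rf, collapse = "x"), np))
  invisible(x)
}

.softmax4 <- function(x, channels) {
  d <- dim(x)
  n <- prod(d[1:3])
  m <- matrix(x[, , , channels, drop = FALSE], nrow = n)
  m <- exp(m - apply(m, 1, max))
  m <- m / rowSums(m)
  array(m, dim = c(d[1:3], length(channels)))
}

# Forward pass through the raw layer stack (no heads). Returns the head
# pre-activation and, optionally, the cached layer inputs/outputs.
.net_forward_raw <- function(net, x, cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  caches <- if (cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (cache) caches[[i]] <- list(x = x)
    if (l$type == "conv") {
      x <- cpp_conv3d_fw(as.numeric(x), dim(x), as.numeric(l$W), dim(l$W),
                         l$b, identical(l$activation, "relu"))
      if (identical(l$activation, "lrelu")) {
        neg <- x < 0
        x[neg] <- 0.1 * x[neg]
      }
    } else if (l$type == "pool") {
      x <- cpp_pool_avg_fw(as.numeric(x), dim(x), l$size)
    } else {
      x <- cpp_upsample_fw(as.numeric(x), dim(x), l$size)
    }
    x <- array(x, dim = attr(x, "dim") %||% dim(x))
    if (cache) caches[[i]]$out <- x
  }
  list(head = x, caches = caches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a network to one input patch
#'
#' @param net an [build_network()] result.
#' @param x 3D numeric array (normalised input patch).
#' @return A list with `probs` (4D array, SoftMax channels summing to 1 at
#'   every voxel) and, for instance networks, `linear` (4D array of the
#'   centre-regression channels).
#' @export
network_apply <- function(net, x) {
  fw <- .net_forward_raw(net, x)
  head <- fw$head
  cfg <- net$config
  probs <- .softmax4(head, seq_len(cfg$n_softmax))
  out <- list(probs = probs)
  if (cfg$n_linear > 0L)
    out$linear <- head[, , , cfg$n_softmax + seq_len(cfg$n_linear), drop = FALSE]
  out
}

# Backward pass: ghead is the gradient at the head pre-activation.
# Returns per-layer gradients (NULL for parameter-free layers).
.net_backward_raw <- function(net, caches, ghead) {
  g <- ghead
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cc <- caches[[i]]
    if (l$type == "conv") {
      if (identical(l$activation, "relu")) g <- g * (cc$out > 0)
      if (identical(l$activation, "lrelu")) g <- g * ifelse(cc$out > 0, 1, 0.1)
      bw <- cpp_conv3d_bw(as.numeric(cc$x), dim(cc$x), as.numeric(l$W),
                          dim(l$W), as.numeric(g))
      grads[[i]] <- list(gw = array(bw$gw, dim(l$W)), gb = bw$gb)
      g <- array(bw$gx, dim(cc$x))
    } else if (l$type == "pool") {
      g <- array(cpp_pool_avg_bw(as.numeric(g), dim(cc$x), l$size), dim(cc$x))
    } else {
      g <- array(cpp_upsample_bw(as.numeric(g), dim(cc$x), l$size), dim(cc$x))
    }
  }
  grads
}

#' Masked categorical cross-entropy (plus optional centre regression)
#'
#' The segmentation loss is the mean of `-log p(true class)` over voxels
#' whose validity mask is 1, which is how partially annotated studies are
#' handled: unannotated labels contribute nothing. Instance networks add a
#' masked mean-squared-error term on the centre-offset channels over
#' vertebra/rib foreground voxels.
#'
#' @param probs 4D array of class probabilities (channels sum to 1).
#' @param target 3D integer array of true class indices (1-based channels).
#' @param mask 3D 0/1 validity array (`NULL` = all valid).
#' @param centre_pred,centre_target optional 4D arrays (last dim 3) of
#'   predicted and true centre values.
#' @param centre_mask optional 3D 0/1 array selecting instance-foreground
#'   voxels for the regression term.
#' @param centre_weight weight of the regression term (default 1).
#' @return Scalar loss. An all-zero mask yields 0 with a warning.
#' @export
masked_loss <- function(probs, target, mask = NULL,
                        centre_pred = NULL, centre_target = NULL,
                        centre_mask = NULL, centre_weight = 1) {
  d <- dim(probs)
  n <- prod(d[1:3])
  if (is.null(mask)) mask <- array(1, d[1:3])
  tv <- as.integer(target)
  lin <- seq_len(n) + (tv - 1L) * n
  mv <- as.numeric(mask)
  tot <- sum(mv)
  if (tot == 0) {
    warning("all-zero validity mask; loss is 0")
    ce <- 0
  } else {
    p <- pmax(probs[lin], 1e-12)
    ce <- sum(-log(p) * mv) / tot
  }
  reg <- 0
  if (!is.null(centre_pred)) {
    cm <- if (is.null(centre_mask)) array(1, d[1:3]) else centre_mask
    cmt <- sum(cm)
    if (cmt > 0) {
      se <- 0
      for (a in 1:3) {
        diff <- (centre_pred[, , , a] - centre_target[, , , a])
        diff[cm == 0] <- 0
        diff[is.na(diff)] <- 0
        se <- se + sum(diff^2)
      }
      reg <- centre_weight * se / (3 * cmt)
    }
  }
  ce + reg
}

#' Training configuration
#'
#' Optimisation uses categorical cross-entropy (with validity-mask
#' weighting) minimised by the adaptive-moment method with Nesterov momentum
#' (Nadam); studies are split 80% training / 20% validation at the study
#' level. The full-scale defaults are batch size 50 and 136x136x72 patches;
#' the desk-scale experiments shipped with the package use smaller values.
#'
#' @param epochs number of epochs.
#' @param iters_per_epoch optimisation steps per epoch.
#' @param batch_size patches per step.
#' @param lr learning rate.
#' @param beta1,beta2,eps Nadam moment decay rates and stabiliser.
#' @param val_fraction fraction of studies held out for validation.
#' @param patch_size patch size; defaults to the network config's.
#' @param fg_bias foreground-biased patch sampling probability.
#' @param augment an [augmentation_params()] or `NULL` to disable.
#' @param centre_weight weight of the centre-regression loss term.
#' @param class_balance weight each voxel's cross-entropy by the inverse
#'   frequency of its class within the patch's valid region. Under severe
#'   class imbalance this keeps the argmax decision boundary at the class
#'   boundary even while logit magnitudes are still growing, which matters
#'   for low-contrast organs (air vs lung) in short CPU-scale trainings.
#' @param seed integer seed controlling the split, sampling, augmentation
#'   and initial shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 8L, iters_per_epoch = 25L, batch_size = 4L,
                            lr = 2e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                            val_fraction = 0.2, patch_size = NULL,
                            fg_bias = 0.5, augment = NULL, centre_weight = 1,
                            class_balance = FALSE, seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, val_fraction = val_fraction,
                 patch_size = patch_size, fg_bias = fg_bias, augment = augment,
                 centre_weight = centre_weight,
                 class_balance = isTRUE(class_balance), seed = as.integer(seed)),
            class = "training_config")
}

.crop_to_output <- function(arr, margin, osz) {
  arr[margin[1] + seq_len(osz[1]), margin[2] + seq_len(osz[2]),
      margin[3] + seq_len(osz[3]), drop = FALSE]
}

# Build the head-preactivation gradient and the loss for one patch.
.patch_loss_grad <- function(net, patch, cfg, tcfg) {
  c_cfg <- net$config
  x <- clamp_scale(patch$image)
  fw <- .net_forward_raw(net, x, cache = TRUE)
  head <- fw$head
  osz <- dim(head)[1:3]
  margin <- net$margin
  probs <- .softmax4(head, seq_len(c_cfg$n_softmax))
  mask <- .crop_to_output(patch$mask, margin, osz)
  if (c_cfg$kind == "semantic") {
    lab <- .crop_to_output(patch$labels, margin, osz)
    tgt <- array(match(as.vector(lab), c_cfg$label_values, nomatch = 0L) + 1L, osz)
  } else {
    tgt <- .crop_to_output(patch$instance_class, margin, osz)
  }
  n <- prod(osz)
  if (isTRUE(tcfg$class_balance)) {
    # inverse-frequency class weights over the valid region, mean weight 1
    valid <- mask > 0
    if (any(valid)) {
      freq <- table(tgt[valid])
      w <- (sum(freq) / (length(freq) * freq))[as.character(tgt)]
      mask <- mask * array(as.numeric(w), osz)
    }
  }
  mv <- as.numeric(mask)
  tot <- max(1, sum(mv))
  onehot <- array(0, dim(probs))
  lin <- seq_len(n) + (as.integer(tgt) - 1L) * n
  onehot[lin] <- 1
  ghead <- array(0, dim(head))
  gsoft <- (probs - onehot) * array(rep(mv, c_cfg$n_softmax), dim(probs)) / tot
  ghead[, , , seq_len(c_cfg$n_softmax)] <- gsoft
  loss <- masked_loss(probs, tgt, mask)
  if (c_cfg$n_linear > 0L) {
    pred <- head[, , , c_cfg$n_softmax + 1:3, drop = FALSE]
    off <- patch$centre_offset
    ctgt <- array(NA_real_, c(osz, 3L))
    for (a in 1:3)
      ctgt[, , , a] <- .crop_to_output(off[, , , a], margin, osz) /
        c_cfg$centre_scale
    cmask <- (tgt > 1L) * mask
    cmask[is.na(.crop_to_output(off[, , , 1], margin, osz))] <- 0
    ctot <- max(1, sum(cmask))
    for (a in 1:3) {
      diff <- pred[, , , a] - ctgt[, , , a]
      diff[cmask == 0 | is.na(diff)] <- 0
      ghead[, , , c_cfg$n_softmax + a] <- tcfg$centre_weight * 2 * diff / (3 * ctot)
    }
    loss <- loss + masked_loss(probs, tgt, mask, centre_pred = pred,
                               centre_target = ctgt, centre_mask = cmask,
                               centre_weight = tcfg$centre_weight) -
      masked_loss(probs, tgt, mask)
  }
  list(loss = loss, grads = .net_backward_raw(net, fw$caches, ghead))
}

#' Train a network on phantom studies
#'
#' Studies are split at the study level (80/20 by default); each step
#' samples a batch of random patches from random training studies, applies
#' optional augmentation, and takes one Nadam step on the masked loss.
#' Training is fully seeded and deterministic; a NaN loss aborts with an
#' error rather than being swallowed.
#'
#' @param net a [build_network()] result with unit output stride.
#' @param data list of [generate_phantom()] results (optionally with
#'   sparsified `annotation` fields).
#' @param config a [training_config()].
#' @return A list of class `trained_network` with fields `net` (updated
#'   weights), `history` (data frame: epoch, train_loss, val_loss) and
#'   `split` (train/validation study indices).
#' @export
train_network <- function(net, data, config = training_config()) {
  stopifnot(inherits(net, "fcn_network"), inherits(config, "training_config"))
  if (!net$unit_stride || anyNA(net$margin))
    stop("training requires a unit-stride stack with odd receptive field")
  if (!length(data)) stop("empty training set")
  set.seed(config$seed)
  n <- length(data)
  n_val <- if (n > 1L) max(1L, floor(config$val_fraction * n)) else 0L
  perm <- sample.int(n)
  val_idx <- if (n_val > 0L) perm[seq_len(n_val)] else integer()
  train_idx <- setdiff(perm, val_idx)
  if (!length(train_idx)) stop("empty training split")
  psz <- config$patch_size %||% net$config$patch_size

  # Nadam state
  widx <- which(vapply(net$layers, function(l) l$type == "conv", logical(1)))
  mW <- lapply(widx, function(i) array(0, dim(net$layers[[i]]$W)))
  vW <- lapply(widx, function(i) array(0, dim(net$layers[[i]]$W)))
  mb <- lapply(widx, function(i) numeric(length(net$layers[[i]]$b)))
  vb <- lapply(widx, function(i) numeric(length(net$layers[[i]]$b)))
  step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())

  draw_patch <- function(study) {
    p <- sample_patch(study$ct, study$labels, study$annotation, psz,
                      fg_bias = config$fg_bias,
                      truth = if (net$config$kind == "instance") study else NULL)
    if (!is.null(config$augment) && net$config$kind == "semantic")
      p <- augment(p, config$augment)
    p
  }

  for (ep in seq_len(config$epochs)) {
    ep_losses <- numeric(config$iters_per_epoch)
    for (it in seq_len(config$iters_per_epoch)) {
      acc <- NULL
      bl <- 0
      for (bi in seq_len(config$batch_size)) {
        study <- data[[train_idx[sample.int(length(train_idx), 1L)]]]
        pg <- .patch_loss_grad(net, draw_patch(study), net$config, config)
        bl <- bl + pg$loss
        if (is.null(acc)) acc <- pg$grads
        else for (i in widx) {
          acc[[i]]$gw <- acc[[i]]$gw + pg$grads[[i]]$gw
          acc[[i]]$gb <- acc[[i]]$gb + pg$grads[[i]]$gb
        }
      }
      bl <- bl / config$batch_size
      if (!is.finite(bl)) stop("training diverged: non-finite loss at epoch ",
                               ep, ", step ", it)
      ep_losses[it] <- bl
      step <- step + 1L
      b1 <- config$beta1; b2 <- config$beta2
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      for (k in seq_along(widx)) {
        i <- widx[k]
        gw <- acc[[i]]$gw / config$batch_size
        gb <- acc[[i]]$gb / config$batch_size
        mW[[k]] <- b1 * mW[[k]] + (1 - b1) * gw
        vW[[k]] <- b2 * vW[[k]] + (1 - b2) * gw^2
        mb[[k]] <- b1 * mb[[k]] + (1 - b1) * gb
        vb[[k]] <- b2 * vb[[k]] + (1 - b2) * gb^2
        # Nesterov-accelerated adaptive moments
        upW <- (b1 * mW[[k]] / c1 + (1 - b1) * gw / c1) / (sqrt(vW[[k]] / c2) + config$eps)
        upb <- (b1 * mb[[k]] / c1 + (1 - b1) * gb / c1) / (sqrt(vb[[k]] / c2) + config$eps)
        net$layers[[i]]$W <- net$layers[[i]]$W - config$lr * upW
        net$layers[[i]]$b <- net$layers[[i]]$b - config$lr * upb
      }
    }
    vl <- NA_real_
    if (length(val_idx)) {
      vls <- vapply(seq_len(min(4L, 2L * length(val_idx))), function(j) {
        study <- data[[val_idx[((j - 1L) %% length(val_idx)) + 1L]]]
        p <- sample_patch(study$ct, study$labels, study$annotation, psz,
                          fg_bias = config$fg_bias,
                          truth = if (net$config$kind == "instance") study else NULL)
        .patch_loss_grad(net, p, net$config, config)$loss
      }, numeric(1))
      vl <- mean(vls)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                   val_loss = vl))
  }
  structure(list(net = net, history = hist,
                 split = list(train = sort(train_idx), validation = sort(val_idx))),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf("trained_network [%s]: %d epochs, final train loss %.4f\n",
              x$net$config$kind, nrow(x$history),
              utils::tail(x$history$train_loss, 1)))
  invisible(x)
}

#' Whole-volume inference by exact tiling
#'
#' The volume is mirror-padded by the valid-convolution margin and tiled;
#' because the convolutions are valid and the stack has unit output stride,
#' every output voxel depends only on its own receptive-field window, so the
#' result is independent of the tiling plan and identical to an untiled
#' pass.
#'
#' @param net a [build_network()] or [train_network()] result.
#' @param vol a [volume()] at the training spacing. CT volumes are
#'   normalised internally; `NORMALIZED` volumes are used as-is.
#' @param tile integer length-3 maximum output-chunk size per axis.
#' @return For semantic networks, a list of class `semantic_field` with
#'   `probs` (4D, channels = background + labels), `label_values` and
#'   `grid`. For instance networks, an `instance_field` with `probs`
#'   (background/vertebra/rib), `centres` (4D, predicted owning-instance
#'   centre in world mm per voxel) and `grid`.
#' @export
predict_volume <- function(net, vol, tile = c(48, 48, 48)) {
  if (inherits(net, "trained_network")) net <- net$net
  stopifnot(inherits(net, "fcn_network"), inherits(vol, "volume"))
  if (!net$unit_stride || anyNA(net$margin))
    stop("tiled inference requires a unit-stride stack with odd receptive field")
  cfg <- net$config
  x <- if (vol$modality == "NORMALIZED") vol$values else clamp_scale(vol)$values
  d <- dim(x)
  m <- net$margin
  pad <- .mirror_pad(x, m)
  C <- cfg$n_softmax + cfg$n_linear
  head <- array(NA_real_, c(d, C))
  tile <- pmin(as.integer(tile), d)
  starts <- lapply(1:3, function(a) seq(0L, d[a] - 1L, by = tile[a]))
  for (ox in starts[[1]]) for (oy in starts[[2]]) for (oz in starts[[3]]) {
    osz <- pmin(tile, d - c(ox, oy, oz))
    blk <- pad[ox + seq_len(osz[1] + 2L * m[1]),
               oy + seq_len(osz[2] + 2L * m[2]),
               oz + seq_len(osz[3] + 2L * m[3]), drop = FALSE]
    hw <- .net_forward_raw(net, blk)$head
    head[ox + seq_len(osz[1]), oy + seq_len(osz[2]), oz + seq_len(osz[3]), ] <- hw
  }
  probs <- .softmax4(head, seq_len(cfg$n_softmax))
  if (cfg$kind == "semantic") {
    structure(list(probs = probs, label_values = cfg$label_values,
                   grid = vol$grid), class = "semantic_field")
  } else {
    lin <- head[, , , cfg$n_softmax + 1:3, drop = FALSE] * cfg$centre_scale
    centres <- array(NA_real_, c(d, 3L))
    if (cfg$centre_mode == "offset") {
      g <- vol$grid
      for (a in 1:3) {
        pos <- g$origin[a] + (seq_len(d[a]) - 1L) * g$spacing[a]
        posarr <- switch(a,
                         array(rep(pos, times = d[2] * d[3]), d),
                         array(rep(rep(pos, each = d[1]), times = d[3]), d),
                         array(rep(pos, each = d[1] * d[2]), d))
        centres[, , , a] <- posarr + lin[, , , a]
      }
    } else {
      centres <- lin
    }
    structure(list(probs = probs, centres = centres, grid = vol$grid),
              class = "instance_field")
  }
}

#' Hard label map from semantic probabilities
#'
#' Argmax over channels with ties broken toward the lower channel (and thus
#' lower label) index; channel 1 is background.
#'
#' @param field a `semantic_field` from [predict_volume()].
#' @param registry optional [label_registry] attached to the result.
#' @return A [label_map()].
#' @export
argmax_labels <- function(field, registry = NULL) {
  stopifnot(inherits(field, "semantic_field"))
  ch <- array(cpp_argmax4(as.numeric(field$probs), dim(field$probs)),
              dim(field$probs)[1:3])
  lab <- array(0L, dim(ch))
  fg <- ch > 1L
  lab[fg] <- field$label_values[ch[fg] - 1L]
  label_map(lab, field$grid, registry, check = FALSE)
}

#' Save / load a network checkpoint
#'
#' Weights are stored in R's native serialisation with a JSON sidecar
#' describing the configuration.
#'
#' @param net a [build_network()] or [train_network()] result.
#' @param dir checkpoint directory (created if needed).
#' @return `save_network` returns `dir` invisibly; `load_network` returns an
#'   `fcn_network`.
#' @export
save_network <- function(net, dir) {
  if (inherits(net, "trained_network")) net <- net$net
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(net, file.path(dir, "weights.rds"))
  cfg <- net$config
  side <- list(kind = cfg$kind, n_labels = cfg$n_labels,
               label_values = cfg$label_values,
               n_softmax = cfg$n_softmax, n_linear = cfg$n_linear,
               patch_size = cfg$patch_size, spacing = cfg$spacing,
               receptive_field = net$rf, centre_scale = cfg$centre_scale,
               centre_mode = cfg$centre_mode)
  jsonlite::write_json(side, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_network
#' @export
load_network <- function(dir) {
  net <- readRDS(file.path(dir, "weights.rds"))
  stopifnot(inherits(net, "fcn_network"))
  net
}
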