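#' Intensity normalisation parameters
#'
#' Hounsfield values are clamped to `[clamp_low, clamp_high]` and divided by
#' `scale`, yielding network inputs in \[-1, 1\]. Defaults: clamp to
#' \[-800, 800\] HU and divide by 800.
#'
#' @param clamp_low lower clamp bound (HU).
#' @param clamp_high upper clamp bound (HU).
#' @param scale positive divisor.
#' @return A list of class `normalization_params`.
#' @export
normalization_params <- function(clamp_low = -800, clamp_high = 800, scale = 800) {
  if (clamp_low >= clamp_high) stop("clamp_low must be < clamp_high")
  if (scale <= 0) stop("scale must be > 0")
  structure(list(clamp_low = clamp_low, clamp_high = clamp_high, scale = scale),
            class = "normalization_params")
}

#' Clamp and scale a CT volume to the normalised input range
#'
#' `out = clip(in, clamp_low, clamp_high) / scale`. The map is total,
#' monotone non-decreasing, and idempotent on already-normalised input
#' (values in \[-1, 1\] with the default parameters).
#'
#' @param vol a [volume()] (CT_HU or NORMALIZED) or a numeric array.
#' @param params a [normalization_params()].
#' @return A `NORMALIZED` [volume()] (or array when the input was an array).
#' @examples
#' p <- normalization_params()
#' v <- volume(array(c(-2000, 0, 400, 800, 2000), c(5, 1, 1)),
#'             image_grid(c(5, 1, 1), c(1, 1, 1)))
#' as.vector(clamp_scale(v, p)$values)
#' @export
clamp_scale <- function(vol, params = normalization_params()) {
  f <- function(x) pmin(pmax(x, params$clamp_low), params$clamp_high) / params$scale
  if (inherits(vol, "volume")) {
    if (vol$modality == "NORMALIZED") {
      # treat values as already-scaled HU so a second application is a no-op
      v <- pmin(pmax(vol$values, params$clamp_low / params$scale),
                params$clamp_high / params$scale)
      return(volume(v, vol$grid, "NORMALIZED"))
    }
    if (vol$modality != "CT_HU") stop("clamp_scale expects a CT_HU volume")
    volume(f(vol$values), vol$grid, "NORMALIZED")
  } else {
    f(vol)
  }
}

#' Resample a volume onto a new spacing by trilinear interpolation
#'
#' Images acquired at arbitrary spacing are resampled to the training
#' spacing, (1.36, 1.36, 3) mm by default, before the networks run. The
#' output grid keeps the input origin and covers the same physical extent
#' (voxel counts rounded to the nearest integer, minimum 1).
#'
#' @param vol a [volume()].
#' @param target_spacing numeric length-3 spacing in mm (all > 0).
#' @return A [volume()] on the new grid, same modality.
#' @export
resample_image <- function(vol, target_spacing = c(1.36, 1.36, 3)) {
  stopifnot(inherits(vol, "volume"))
  target_spacing <- as.numeric(target_spacing)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  g <- vol$grid
  if (isTRUE(all.equal(target_spacing, g$spacing))) return(vol)
  new_shape <- pmax(1L, as.integer(round(g$shape * g$spacing / target_spacing)))
  out <- cpp_resample(as.numeric(vol$values), g$shape, g$spacing, g$origin,
                      new_shape, target_spacing, g$origin, FALSE)
  volume(array(out, new_shape),
         image_grid(new_shape, target_spacing, g$origin), vol$modality)
}

#' Resample a label map back onto an image grid by nearest neighbour
#'
#' Segmentations computed at the training spacing are mapped back to the
#' original image resolution with nearest-neighbour interpolation, so no
#' label indices outside the input (plus background) ever appear.
#'
#' @param labels a [label_map()].
#' @param grid the target [image_grid()].
#' @return A [label_map()] on `grid`.
#' @export
resample_labels_back <- function(labels, grid) {
  stopifnot(inherits(labels, "label_map"), inherits(grid, "image_grid"))
  sg <- labels$grid
  s_lo <- sg$origin; s_hi <- sg$origin + (sg$shape - 1) * sg$spacing
  d_lo <- grid$origin; d_hi <- grid$origin + (grid$shape - 1) * grid$spacing
  if (any(d_hi < s_lo - sg$spacing) || any(d_lo > s_hi + sg$spacing))
    stop("label and target grids do not overlap")
  out <- cpp_resample(as.numeric(labels$labels), sg$shape, sg$spacing, sg$origin,
                      grid$shape, grid$spacing, grid$origin, TRUE)
  label_map(array(as.integer(round(out)), grid$shape), grid, labels$registry,
            check = FALSE)
}

#' Augmentation parameter ranges
#'
#' Training patches are enriched with moderate in-plane rotations
#' (+-0.15 rad), isotropic scaling (+-10%), and intensity shifts
#' (+-100 HU). Intensity shifts are applied in the HU domain, before
#' clamping and normalisation, because the +-100 HU range only has meaning
#' pre-scaling.
#'
#' @param rotation_rad half-width of the uniform rotation range (radians).
#' @param scale_frac half-width of the uniform scaling range (fraction).
#' @param intensity_hu half-width of the uniform intensity-shift range (HU).
#' @return A list of class `augmentation_params`.
#' @export
augmentation_params <- function(rotation_rad = 0.15, scale_frac = 0.10,
                                intensity_hu = 100) {
  if (rotation_rad < 0 || scale_frac < 0 || intensity_hu < 0)
    stop("augmentation ranges must be non-negative")
  structure(list(rotation_rad = rotation_rad, scale_frac = scale_frac,
                 intensity_hu = intensity_hu),
            class = "augmentation_params")
}

.mirror_index <- function(n, m_lo, m_hi) {
  # 1-based indices of a mirror-padded axis of original length n
  idx <- seq(1L - m_lo, n + m_hi)
  per <- c(seq_len(n), seq(n - 1L, 2L))       # reflection period 2n - 2
  if (n == 1L) return(rep(1L, length(idx)))
  per[((idx - 1L) %% (2L * n - 2L)) + 1L]
}

.mirror_pad <- function(arr, pad) {
  d <- dim(arr)
  arr[.mirror_index(d[1], pad[1], pad[1]),
      .mirror_index(d[2], pad[2], pad[2]),
      .mirror_index(d[3], pad[3], pad[3]), drop = FALSE]
}

#' Sample a training patch with annotation-aware validity mask
#'
#' Patch origins are uniform over valid positions; with probability
#' `fg_bias` the patch is instead centred on a random foreground voxel
#' (clamped inside the volume), which counteracts class imbalance. Volumes
#' smaller than the patch are mirror-padded. The loss-validity mask is zero
#' wherever the study lacks annotation for the voxel's true label.
#'
#' Randomness comes from the R session RNG: call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param vol a [volume()] (any modality; sampled as-is).
#' @param labels a [label_map()] aligned to `vol`.
#' @param annotation an [annotation_mask()] or `NULL` (fully annotated).
#' @param size integer length-3 patch size in voxels.
#' @param fg_bias probability of foreground-centred sampling in \[0, 1\].
#' @param truth optional [generate_phantom()] result; when supplied, the
#'   patch additionally carries per-voxel instance-class targets
#'   (1 background, 2 vertebra, 3 rib) and centre-offset targets in mm
#'   (instance centre minus voxel position; NA outside instances).
#' @return A list of class `patch_sample` with fields `image`, `labels`,
#'   `mask`, `origin0` (0-based corner in the unpadded volume, may be
#'   negative under padding), `grid`, and optionally `instance_class`,
#'   `centre_offset` (4D, last dim 3).
#' @export
sample_patch <- function(vol, labels, annotation = NULL, size = c(24, 24, 24),
                         fg_bias = 0.5, truth = NULL) {
  stopifnot(inherits(vol, "volume"), inherits(labels, "label_map"))
  size <- as.integer(size)
  d <- vol$grid$shape
  pad <- pmax(0L, size - d)
  pad_lo <- as.integer(ceiling(pad / 2))   # same padding both sides
  img <- vol$values
  lab <- labels$labels
  if (any(pad > 0L)) {
    img <- .mirror_pad(img, pad_lo)
    lab <- .mirror_pad(lab, pad_lo)
  }
  dd <- dim(img)
  max0 <- dd - size  # max 0-based origin
  fg <- NULL
  if (fg_bias > 0 && stats::runif(1) < fg_bias) {
    fgv <- which(lab > 0L)
    if (length(fgv)) fg <- fgv[sample.int(length(fgv), 1L)]
  }
  if (!is.null(fg)) {
    co <- arrayInd(fg, dd) - 1L
    org <- pmin(pmax(co - size %/% 2L, 0L), max0)
  } else {
    org <- c(sample.int(max0[1] + 1L, 1L), sample.int(max0[2] + 1L, 1L),
             sample.int(max0[3] + 1L, 1L)) - 1L
  }
  ix <- org[1] + seq_len(size[1]); iy <- org[2] + seq_len(size[2])
  iz <- org[3] + seq_len(size[3])
  pimg <- img[ix, iy, iz, drop = FALSE]
  plab <- lab[ix, iy, iz, drop = FALSE]
  mask <- annotation_weights(annotation, plab)
  out <- list(image = pimg, labels = plab, mask = mask,
              origin0 = org - pad_lo,
              grid = vol$grid, size = size)
  if (!is.null(truth)) {
    if (any(pad > 0L)) stop("instance targets are unsupported with padding")
    iid <- truth$instance_id[ix, iy, iz, drop = FALSE]
    cls <- array(1L, dim = size)
    offs <- array(NA_real_, dim = c(size, 3L))
    if (nrow(truth$instance_centres)) {
      ic <- truth$instance_centres
      cls_code <- c(vertebra = 2L, rib = 3L)
      wpos <- voxel_world_mm(vol$grid,
                             cbind(rep(org[1] + seq_len(size[1]) - 1L, times = size[2] * size[3]),
                                   rep(rep(org[2] + seq_len(size[2]) - 1L, each = size[1]),
                                       times = size[3]),
                                   rep(org[3] + seq_len(size[3]) - 1L, each = size[1] * size[2])))
      iidv <- as.vector(iid)
      hit <- iidv > 0L
      if (any(hit)) {
        row <- match(iidv[hit], ic$id)
        cls[hit] <- cls_code[ic$class[row]]
        cm <- cbind(ic$cx[row], ic$cy[row], ic$cz[row])
        off <- cm - wpos[hit, , drop = FALSE]
        for (a in 1:3) {
          tmp <- array(NA_real_, dim = size)
          tmp[hit] <- off[, a]
          offs[, , , a] <- tmp
        }
      }
    }
    out$instance_class <- cls
    out$centre_offset <- offs
  }
  class(out) <- "patch_sample"
  out
}

#' Augment a training patch
#'
#' Applies one random in-plane rotation and isotropic scale drawn uniformly
#' from the parameter ranges -- identically to the image (trilinear) and to
#' the categorical label and mask channels (nearest neighbour) -- plus a
#' uniform intensity shift applied to the image only, in HU. Zero-width
#' ranges reproduce the input exactly.
#'
#' @param patch a [sample_patch()] result (image in the HU domain).
#' @param params an [augmentation_params()].
#' @return A `patch_sample` with a `draws` attribute recording the sampled
#'   rotation, scale factor and intensity shift.
#' @export
augment <- function(patch, params = augmentation_params()) {
  stopifnot(inherits(patch, "patch_sample"))
  rot <- if (params$rotation_rad > 0)
    stats::runif(1, -params$rotation_rad, params$rotation_rad) else 0
  scl <- 1 + if (params$scale_frac > 0)
    stats::runif(1, -params$scale_frac, params$scale_frac) else 0
  shift <- if (params$intensity_hu > 0)
    stats::runif(1, -params$intensity_hu, params$intensity_hu) else 0
  d <- dim(patch$image)
  out <- patch
  if (rot != 0 || scl != 1) {
    out$image <- array(cpp_warp_inplane(as.numeric(patch$image), d, rot, scl, FALSE), d)
    out$labels <- array(as.integer(cpp_warp_inplane(as.numeric(patch$labels), d,
                                                    rot, scl, TRUE)), d)
    out$mask <- array(cpp_warp_inplane(as.numeric(patch$mask), d, rot, scl, TRUE), d)
  }
  out$image <- out$image + shift
  attr(out, "draws") <- c(rotation = rot, scale = scl, shift = shift)
  out
}

#' Binary mask of voxels inside a Hounsfield range
#'
#' The thresholding-brush kernel: paints only voxels whose HU value lies in
#' the given closed range, optionally intersected with a user-supplied
#' region mask.
#'
#' @param vol a CT [volume()].
#' @param hu_range numeric `c(low, high)` with `low <= high`; infinities
#'   allowed.
#' @param region optional logical array restricting the mask.
#' @return Logical array of the volume's shape.
#' @export
threshold_mask <- function(vol, hu_range, region = NULL) {
  stopifnot(inherits(vol, "volume"))
  if (vol$modality != "CT_HU") stop("threshold_mask expects a CT_HU volume")
  if (hu_range[1] > hu_range[2]) stop("hu_range low must be <= high")
  m <- vol$values >= hu_range[1] & vol$values <= hu_range[2]
  if (!is.null(region)) m <- m & region
  m
}
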