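#' Synthetic CT/PET phantom specification
#'
#' A phantom is built from simple geometric primitives (ellipsoids, boxes,
#' tubes) with known Hounsfield statistics, plus an optional spine of
#' repeated vertebra-like instances with rib tubes, emulating the
#' multiple-similar-instance structure that the instance network targets.
#' Ground truth (labels, per-instance centres, annotation pattern) is exact
#' by construction, so every downstream stage is testable without patient
#' data.
#'
#' @param grid an [image_grid()]; the default desk-scale grid is 64^3 voxels
#'   at (2, 2, 3) mm.
#' @param organs list of organ primitives, each a list with fields `label`
#'   (registry index), `shape` (`"ellipsoid"`, `"box"` or `"tube"`),
#'   `centre_mm`, `radii_mm` (half-extents; for tubes the component along
#'   `axis` is the half-length, the others the cross-section radii),
#'   `hu_mean`, optional `hu_jitter_sd` (per-voxel HU jitter, default 0) and
#'   optional `axis` (`"x"`, `"y"` or `"z"`, tubes only).
#' @param spine optional spine specification from [spine_spec()].
#' @param background_hu background Hounsfield value (-1000 = air, 0 = water).
#' @param noise_sd global additive Gaussian noise standard deviation in HU.
#' @param seed integer seed making generation deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = image_grid(c(64, 64, 64), c(2, 2, 3)),
                         organs = list(), spine = NULL,
                         background_hu = -1000, noise_sd = 20, seed = 1L) {
  stopifnot(inherits(grid, "image_grid"))
  for (o in organs) {
    if (!all(c("label", "shape", "centre_mm", "radii_mm", "hu_mean") %in% names(o)))
      stop("each organ needs label, shape, centre_mm, radii_mm, hu_mean")
    if (!o$shape %in% c("ellipsoid", "box", "tube"))
      stop("unknown shape: ", o$shape)
    lo <- o$centre_mm - o$radii_mm
    hi <- o$centre_mm + o$radii_mm
    ext <- grid$origin + (grid$shape - 1) * grid$spacing
    if (any(lo < grid$origin - grid$spacing) || any(hi > ext + grid$spacing))
      stop("organ primitive (label ", o$label, ") lies outside the grid")
  }
  structure(list(grid = grid, organs = organs, spine = spine,
                 background_hu = background_hu, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Spine specification for the phantom generator
#'
#' Vertebrae are axially stacked ellipsoids centred on the grid's (x, y)
#' midline with a small random z-jitter; ribs are tubes attached left and
#' right at vertebra z-levels. The centre-to-centre pitch is
#' `size_mm[3] + gap_mm`.
#'
#' @param n_vertebrae number of vertebra instances (>= 0).
#' @param size_mm full vertebra extents (x, y, z) in mm.
#' @param gap_mm clear gap between consecutive vertebrae in mm.
#' @param rib_pairs_range integer range `c(lo, hi)`: each vertebra carries a
#'   uniformly drawn number of left/right rib pairs in this range.
#' @param hu_mean vertebra/rib mean HU (bone-like).
#' @param hu_jitter_sd per-voxel HU jitter inside bone.
#' @param z_jitter_sd standard deviation (mm) of the per-vertebra z-jitter.
#' @param labels optional integer vector of registry labels, one per
#'   vertebra (cranio-caudal); defaults to the lumbar-onward vertebra
#'   indices of [default_registry()].
#' @return A list of class `spine_spec`.
#' @export
spine_spec <- function(n_vertebrae = 5L, size_mm = c(36, 30, 15), gap_mm = 9,
                       rib_pairs_range = c(0L, 0L), hu_mean = 700,
                       hu_jitter_sd = 40, z_jitter_sd = 1, labels = NULL) {
  if (n_vertebrae < 0L) stop("n_vertebrae must be >= 0")
  structure(list(n_vertebrae = as.integer(n_vertebrae), size_mm = size_mm,
                 gap_mm = gap_mm, rib_pairs_range = as.integer(rib_pairs_range),
                 hu_mean = hu_mean, hu_jitter_sd = hu_jitter_sd,
                 z_jitter_sd = z_jitter_sd, labels = labels),
            class = "spine_spec")
}

#' Vertebral centre-to-centre pitch of a spine spec (mm)
#' @param spine a [spine_spec()].
#' @return Scalar pitch in mm.
#' @export
spine_pitch_mm <- function(spine) spine$size_mm[3] + spine$gap_mm

.primitive_mask <- function(grid, shape, centre, radii, axis = "z") {
  cx <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  dx <- cx - centre[1]; dy <- cy - centre[2]; dz <- cz - centre[3]
  if (shape == "ellipsoid") {
    qx <- (dx / radii[1])^2; qy <- (dy / radii[2])^2; qz <- (dz / radii[3])^2
    outer(outer(qx, qy, `+`), qz, `+`) <= 1
  } else if (shape == "box") {
    ax <- abs(dx) <= radii[1]; ay <- abs(dy) <= radii[2]; az <- abs(dz) <= radii[3]
    outer(outer(ax, ay, `&`), az, `&`)
  } else { # tube
    ai <- match(axis, c("x", "y", "z"))
    d <- list(dx, dy, dz); r <- radii
    along <- abs(d[[ai]]) <= r[ai]
    perp <- setdiff(1:3, ai)
    q1 <- (d[[perp[1]]] / r[perp[1]])^2
    q2 <- (d[[perp[2]]] / r[perp[2]])^2
    cross <- outer(q1, q2, `+`) <= 1
    # assemble in (x, y, z) order
    parts <- vector("list", 3)
    if (ai == 1) {
      m <- array(FALSE, grid$shape)
      for (k in seq_len(grid$shape[3])) m[, , k] <- outer(along, cross[, k], `&`)
      m
    } else if (ai == 2) {
      m <- array(FALSE, grid$shape)
      for (k in seq_len(grid$shape[3])) m[, , k] <- outer(cross[, k], along, `&`)
      m
    } else {
      m <- array(FALSE, grid$shape)
      for (k in seq_len(grid$shape[3])) if (along[k]) m[, , k] <- cross
      m
    }
  }
}

.mask_centroid_mm <- function(grid, mask) {
  idx <- which(mask, arr.ind = TRUE) - 1L
  colMeans(sweep(sweep(idx, 2, grid$spacing, `*`), 2, grid$origin, `+`))
}

#' Generate a synthetic CT phantom with exact ground truth
#'
#' Rasterises the spec's primitives in order (later primitives overwrite
#' earlier ones at overlaps), adds per-primitive HU jitter and global noise,
#' and records for every vertebra/rib instance its voxel-centroid centre in
#' world millimetres -- the regression target of the instance network.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth` with fields `ct` (a CT
#'   [volume()]), `labels` (a [label_map()]), `instance_id` (integer array,
#'   0 = no instance), `instance_centres` (data frame: `id`, `class`,
#'   `label`, `cx`, `cy`, `cz` in mm), `annotation` (an [annotation_mask()]
#'   covering all generated labels), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  grid <- spec$grid
  hu <- array(spec$background_hu, grid$shape)
  labels <- array(0L, grid$shape)
  instance_id <- array(0L, grid$shape)
  inst <- list()

  paint <- function(mask, label, hu_mean, jitter_sd) {
    n <- sum(mask)
    if (n == 0L) return(invisible(NULL))
    vals <- rep(hu_mean, n)
    if (jitter_sd > 0) vals <- vals + stats::rnorm(n, 0, jitter_sd)
    hu[mask] <<- vals
    labels[mask] <<- as.integer(label)
  }

  for (o in spec$organs) {
    m <- .primitive_mask(grid, o$shape, o$centre_mm, o$radii_mm,
                         axis = if (is.null(o$axis)) "z" else o$axis)
    paint(m, o$label, o$hu_mean, if (is.null(o$hu_jitter_sd)) 0 else o$hu_jitter_sd)
  }

  sp <- spec$spine
  if (!is.null(sp) && sp$n_vertebrae > 0L) {
    pitch <- spine_pitch_mm(sp)
    ext <- grid_extent_mm(grid)
    mid <- grid$origin + (grid$shape - 1) * grid$spacing / 2
    total <- sp$n_vertebrae * pitch - sp$gap_mm
    z0 <- grid$origin[3] + (ext[3] - total) / 2 + sp$size_mm[3] / 2
    vlabels <- sp$labels
    if (is.null(vlabels)) {
      # default: the n most caudal vertebra entries of the registry, so
      # instance 1 (lowest z, most caudal) gets the last lumbar label
      vidx <- registry_instance_indices(default_registry(), "vertebra")
      if (sp$n_vertebrae > length(vidx))
        stop("more vertebrae than registry vertebra slots; pass explicit labels")
      vlabels <- rev(utils::tail(vidx, sp$n_vertebrae))
    }
    next_id <- length(inst)
    reg_ribs <- registry_instance_indices(default_registry(), "rib")
    for (v in seq_len(sp$n_vertebrae)) {
      zc <- z0 + (v - 1) * pitch + stats::rnorm(1, 0, sp$z_jitter_sd)
      centre <- c(mid[1], mid[2], zc)
      m <- .primitive_mask(grid, "ellipsoid", centre, sp$size_mm / 2)
      if (!any(m)) stop("vertebra ", v, " rasterised to an empty mask")
      next_id <- next_id + 1L
      paint(m, vlabels[v], sp$hu_mean, sp$hu_jitter_sd)
      instance_id[m] <- next_id
      inst[[next_id]] <- list(id = next_id, class = "vertebra",
                              label = as.integer(vlabels[v]),
                              centre = .mask_centroid_mm(grid, m))
      n_pairs <- if (sp$rib_pairs_range[2] > 0L)
        sample(seq(sp$rib_pairs_range[1], sp$rib_pairs_range[2]), 1L)
      else 0L
      if (n_pairs > 0L) {
        rib_len <- sp$size_mm[1] * 0.8
        rib_r <- max(grid$spacing[1:2]) * 1.2
        for (side in c("left", "right")) {
          sgn <- if (side == "left") 1 else -1
          rc <- c(mid[1] + sgn * (sp$size_mm[1] / 2 + rib_len / 2 + grid$spacing[1]),
                  mid[2], zc)
          rm <- .primitive_mask(grid, "tube", rc,
                                c(rib_len / 2, rib_r, rib_r), axis = "x")
          rm <- rm & labels == 0L
          if (any(rm)) {
            next_id <- next_id + 1L
            rl <- if (side == "left") reg_ribs[min(v, 12L)] else reg_ribs[12L + min(v, 12L)]
            paint(rm, rl, sp$hu_mean, sp$hu_jitter_sd)
            instance_id[rm] <- next_id
            inst[[next_id]] <- list(id = next_id, class = "rib",
                                    label = as.integer(rl),
                                    centre = .mask_centroid_mm(grid, rm))
          }
        }
      }
    }
  }

  if (spec$noise_sd > 0)
    hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd), dim(hu))

  centres <- if (length(inst)) {
    data.frame(id = vapply(inst, `[[`, integer(1), "id"),
               class = vapply(inst, `[[`, character(1), "class"),
               label = vapply(inst, `[[`, integer(1), "label"),
               cx = vapply(inst, function(i) i$centre[1], numeric(1)),
               cy = vapply(inst, function(i) i$centre[2], numeric(1)),
               cz = vapply(inst, function(i) i$centre[3], numeric(1)))
  } else {
    data.frame(id = integer(), class = character(), label = integer(),
               cx = numeric(), cy = numeric(), cz = numeric())
  }

  present <- setdiff(unique(as.vector(labels)), 0L)
  structure(list(ct = volume(hu, grid, "CT_HU"),
                 labels = label_map(labels, grid),
                 instance_id = instance_id,
                 instance_centres = centres,
                 annotation = annotation_mask(present),
                 pet = NULL, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d x %d x %d, %d labels, %d instances\n",
              x$ct$grid$shape[1], x$ct$grid$shape[2], x$ct$grid$shape[3],
              length(x$annotation$annotated_labels), nrow(x$instance_centres)))
  invisible(x)
}

#' Generate a co-registered PET volume for a phantom
#'
#' Voxel activity is the per-label uptake plus optional Gaussian noise;
#' voxels outside any labelled organ receive `background`.
#'
#' @param truth a [generate_phantom()] result.
#' @param uptake named numeric vector: names are registry label indices,
#'   values activity concentrations in kBq/ml (non-negative).
#' @param noise_sd additive Gaussian noise sd (kBq/ml).
#' @param background background activity (kBq/ml).
#' @param seed integer seed.
#' @return A [volume()] with modality `PET_ACTIVITY`.
#' @export
generate_pet <- function(truth, uptake, noise_sd = 0, background = 0, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (any(uptake < 0)) stop("uptake must be non-negative")
  set.seed(as.integer(seed))
  act <- array(background, truth$ct$grid$shape)
  lab <- truth$labels$labels
  for (nm in names(uptake)) act[lab == as.integer(nm)] <- uptake[[nm]]
  if (noise_sd > 0)
    act <- act + array(stats::rnorm(length(act), 0, noise_sd), dim(act))
  volume(act, truth$ct$grid, "PET_ACTIVITY")
}

#' Randomly sparsify a phantom's annotation
#'
#' Emulates the situation where not every organ is annotated in every study:
#' each generated label is independently kept with probability
#' `keep_fraction`.
#'
#' @param truth a [generate_phantom()] result.
#' @param keep_fraction probability in (0, 1] of keeping each label.
#' @param seed integer seed.
#' @return An [annotation_mask()].
#' @export
sparsify_annotation <- function(truth, keep_fraction, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  labs <- truth$annotation$annotated_labels
  if (keep_fraction == 1) return(annotation_mask(labs))
  set.seed(as.integer(seed))
  keep <- labs[stats::runif(length(labs)) < keep_fraction]
  annotation_mask(keep)
}
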