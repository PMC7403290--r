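#' Clustering parameters for instance assembly
#'
#' Per-voxel predicted centres are grouped by agglomerative single-linkage
#' clustering with a millimetre distance threshold: voxels whose predicted
#' centres form a chain of links shorter than the threshold belong to one
#' instance, so no preset cluster count is needed -- the number of vertebrae
#' and ribs can vary between images. Clusters smaller than `min_size`
#' voxels are discarded to background.
#'
#' @param linkage_mm single-linkage cut distance in mm (> 0). A good default
#'   is half the expected inter-vertebral centre-to-centre pitch.
#' @param min_size minimum cluster size in voxels.
#' @param max_exact maximum number of points clustered exactly; larger
#'   clouds are quantised to cells of `linkage_mm / 4` first (the linkage
#'   threshold then applies to cell representatives).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(linkage_mm = 12, min_size = 5L, max_exact = 3000L) {
  if (linkage_mm <= 0) stop("linkage_mm must be > 0")
  structure(list(linkage_mm = linkage_mm, min_size = as.integer(min_size),
                 max_exact = as.integer(max_exact)),
            class = "cluster_params")
}

# Single-linkage clustering of an n x 3 point cloud, cut at eps.
# Returns integer cluster ids (1..K).
.cluster_points <- function(P, eps, max_exact = 3000L) {
  n <- nrow(P)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  if (n > max_exact) {
    cell <- pmax(eps / 4, 1e-6)
    key <- paste(floor(P[, 1] / cell), floor(P[, 2] / cell), floor(P[, 3] / cell))
    uk <- !duplicated(key)
    rep_ids <- .cluster_points(P[uk, , drop = FALSE], eps, max_exact = .Machine$integer.max)
    return(rep_ids[match(key, key[uk])])
  }
  hc <- stats::hclust(stats::dist(P), method = "single")
  stats::cutree(hc, h = eps)
}

#' Cluster predicted instance centres into individual vertebrae and ribs
#'
#' Every voxel whose instance-class argmax is vertebra or rib is assigned to
#' exactly one instance: connected groups of predicted centres within the
#' linkage threshold. Vertebrae and ribs are clustered separately.
#'
#' @param field an `instance_field` from [predict_volume()] or
#'   [instance_field_from_truth()].
#' @param params a [cluster_params()].
#' @return A list of class `instance_clusters` with `instance_map` (integer
#'   array, 0 = background), and `instances` (data frame: `id`, `class`,
#'   `n_voxels`, voxel-centroid `cx`, `cy`, `cz` and mean predicted centre
#'   `px`, `py`, `pz`, all mm).
#' @export
cluster_instances <- function(field, params = cluster_params()) {
  stopifnot(inherits(field, "instance_field"))
  d <- dim(field$probs)[1:3]
  cls <- array(cpp_argmax4(as.numeric(field$probs), dim(field$probs)), d)
  imap <- array(0L, d)
  rows <- list()
  next_id <- 0L
  g <- field$grid
  for (code in c(2L, 3L)) {
    vox <- which(cls == code)
    if (!length(vox)) next
    P <- cbind(field$centres[, , , 1][vox], field$centres[, , , 2][vox],
               field$centres[, , , 3][vox])
    ids <- .cluster_points(P, params$linkage_mm, params$max_exact)
    sizes <- tabulate(ids)
    keep <- which(sizes >= params$min_size)
    for (k in keep) {
      next_id <- next_id + 1L
      sel <- vox[ids == k]
      imap[sel] <- next_id
      w <- voxel_world_mm(g, arrayInd(sel, d) - 1L)
      pm <- P[ids == k, , drop = FALSE]
      rows[[next_id]] <- data.frame(
        id = next_id, class = c("vertebra", "rib")[code - 1L],
        n_voxels = length(sel),
        cx = mean(w[, 1]), cy = mean(w[, 2]), cz = mean(w[, 3]),
        px = mean(pm[, 1]), py = mean(pm[, 2]), pz = mean(pm[, 3]))
    }
  }
  inst <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), class = character(), n_voxels = integer(),
               cx = numeric(), cy = numeric(), cz = numeric(),
               px = numeric(), py = numeric(), pz = numeric())
  structure(list(instance_map = imap, instances = inst, grid = g),
            class = "instance_clusters")
}

#' Exact instance field from phantom ground truth
#'
#' Builds the noiseless oracle input for [cluster_instances()]: one-hot
#' class probabilities and, for every instance voxel, the true centre of
#' the owning instance.
#'
#' @param truth a [generate_phantom()] result.
#' @return An `instance_field`.
#' @export
instance_field_from_truth <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  d <- truth$ct$grid$shape
  probs <- array(0, c(d, 3L))
  probs[, , , 1] <- 1
  centres <- array(NA_real_, c(d, 3L))
  ic <- truth$instance_centres
  if (nrow(ic)) {
    code <- c(vertebra = 2L, rib = 3L)
    iid <- as.vector(truth$instance_id)
    hit <- which(iid > 0L)
    row <- match(iid[hit], ic$id)
    n <- prod(d)
    cl <- code[ic$class[row]]
    p1 <- probs[, , , 1]; p1[hit] <- 0; probs[, , , 1] <- p1
    for (cc in c(2L, 3L)) {
      pc <- probs[, , , cc]
      pc[hit[cl == cc]] <- 1
      probs[, , , cc] <- pc
    }
    cm <- cbind(ic$cx[row], ic$cy[row], ic$cz[row])
    for (a in 1:3) {
      ca <- centres[, , , a]
      ca[hit] <- cm[, a]
      centres[, , , a] <- ca
    }
  }
  structure(list(probs = probs, centres = centres, grid = truth$ct$grid),
            class = "instance_field")
}

#' Assign anatomical registry labels to clustered instances
#'
#' Vertebra instances are sorted cranio-caudally (decreasing z; the package
#' convention is +z toward the head) and given consecutive vertebra labels
#' from the registry starting at `start`; anatomical anchoring is heuristic
#' by design (the numbering of a run is ambiguous from images alone). Ribs
#' are assigned the level of the nearest vertebra instance and a side by
#' comparing the centroid x with the vertebral midline (+x = anatomical
#' left). More instances than registry slots triggers a warning and
#' truncation to background.
#'
#' @param clusters an [cluster_instances()] result.
#' @param registry a [label_registry].
#' @param start name of the registry vertebra entry assigned to the most
#'   cranial vertebra instance: `"cervical"`, `"thoracic"` or `"lumbar"`
#'   (its first slot), or an explicit registry index.
#' @return A [label_map()] with vertebra/rib registry labels.
#' @export
assign_indices <- function(clusters, registry = default_registry(),
                           start = "cervical") {
  stopifnot(inherits(clusters, "instance_clusters"))
  vidx <- registry_instance_indices(registry, "vertebra")
  ridx <- registry_instance_indices(registry, "rib")
  if (is.character(start)) {
    pat <- c(cervical = "^Cervical", thoracic = "^Thoracic", lumbar = "^Lumbar")[start]
    if (is.na(pat)) stop("unknown start: ", start)
    first <- vidx[grep(pat, registry$name[vidx])][1]
  } else first <- as.integer(start)
  srun <- vidx[vidx >= first]

  inst <- clusters$instances
  lab <- array(0L, dim(clusters$instance_map))
  vert <- inst[inst$class == "vertebra", , drop = FALSE]
  vert <- vert[order(-vert$cz), , drop = FALSE]    # cranial first
  if (nrow(vert) > length(srun)) {
    warning(sprintf("%d vertebra instances exceed the %d available registry slots; extra instances dropped",
                    nrow(vert), length(srun)))
  }
  v_assign <- integer(0)
  for (i in seq_len(nrow(vert))) {
    if (i > length(srun)) break
    lab[clusters$instance_map == vert$id[i]] <- srun[i]
    v_assign[vert$id[i]] <- i
  }
  ribs <- inst[inst$class == "rib", , drop = FALSE]
  if (nrow(ribs)) {
    if (!nrow(vert)) {
      warning("rib instances present without any vertebra instances; ribs dropped")
    } else {
      mid_x <- mean(vert$cx)
      n_side <- length(ridx) %/% 2L
      for (i in seq_len(nrow(ribs))) {
        lev <- which.min(abs(vert$cz - ribs$cz[i]))
        lev <- min(v_assign[vert$id[lev]], n_side)
        side_left <- ribs$cx[i] > mid_x
        rl <- if (side_left) ridx[lev] else ridx[n_side + lev]
        lab[clusters$instance_map == ribs$id[i]] <- rl
      }
    }
  }
  label_map(lab, clusters$grid, registry, check = FALSE)
}

#' Largest connected component of a binary mask
#'
#' Retains only the largest component under the given connectivity; ties are
#' broken toward the component whose first voxel comes earliest in (z, y, x)
#' scan order. Idempotent; an empty mask stays empty.
#'
#' @param mask logical or 0/1 3D array.
#' @param connectivity 26 (default) or 6.
#' @return Logical array.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  m <- array(as.integer(mask != 0), dim(mask))
  lab <- cpp_cc3d(m, dim(m), as.integer(connectivity))
  k <- attr(lab, "n_components")
  if (k == 0L) return(array(FALSE, dim(mask)))
  sizes <- tabulate(lab, nbins = k)
  best <- which.max(sizes)     # first maximum = earliest seed in scan order
  array(lab == best, dim(mask))
}

#' Fill interior holes of a binary mask
#'
#' Background components not connected to the volume border (6-connectivity
#' on the background by default) are set to foreground.
#'
#' @param mask logical or 0/1 3D array.
#' @param connectivity background connectivity, 6 (default) or 26.
#' @return Logical array.
#' @export
fill_holes <- function(mask, connectivity = 6L) {
  m <- mask != 0
  d <- dim(m)
  bg <- array(as.integer(!m), d)
  lab <- cpp_cc3d(bg, d, as.integer(connectivity))
  k <- attr(lab, "n_components")
  if (k == 0L) return(m)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- setdiff(border, 0L)
  hole <- !m & !(lab %in% border)
  m | array(hole, d)
}

#' Morphological postprocessing of one label mask
#'
#' The final postprocessing applied to every label: keep the largest
#' connected component, then fill holes in it.
#'
#' @param mask logical or 0/1 3D array.
#' @param component_connectivity connectivity for component extraction.
#' @param hole_connectivity background connectivity for hole filling.
#' @return Logical array.
#' @export
postprocess_mask <- function(mask, component_connectivity = 26L,
                             hole_connectivity = 6L) {
  fill_holes(largest_component(mask, component_connectivity), hole_connectivity)
}

#' Fuse semantic and instance segmentations into the final label map
#'
#' Voxels claimed by the instance pathway (nonzero instance label) receive
#' the instance label; all other voxels the semantic argmax (ties toward the
#' lower label index). Each label mask is then postprocessed with
#' largest-component extraction and hole filling; labels are processed in
#' increasing index order and hole filling only claims voxels that are
#' background or already belong to the label.
#'
#' @param semantic a `semantic_field` from [predict_volume()].
#' @param instance_labels a [label_map()] from [assign_indices()], or `NULL`
#'   for semantic-only fusion.
#' @param registry optional [label_registry].
#' @param morphology apply the per-label postprocessing (default TRUE).
#' @return A [label_map()].
#' @export
fuse <- function(semantic, instance_labels = NULL, registry = NULL,
                 morphology = TRUE) {
  stopifnot(inherits(semantic, "semantic_field"))
  sem <- argmax_labels(semantic, registry)
  lab <- sem$labels
  if (!is.null(instance_labels)) {
    stopifnot(inherits(instance_labels, "label_map"))
    if (!identical(instance_labels$grid$shape, semantic$grid$shape))
      stop("semantic and instance grids do not match")
    il <- instance_labels$labels
    lab[il > 0L] <- il[il > 0L]
  }
  if (morphology) {
    out <- array(0L, dim(lab))
    for (k in sort(setdiff(unique(as.vector(lab)), 0L))) {
      mk <- postprocess_mask(lab == k)
      claim <- mk & (out == 0L | lab == k)
      out[claim] <- k
    }
    lab <- out
  }
  label_map(lab, semantic$grid, registry, check = FALSE)
}
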