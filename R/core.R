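#' Image grid geometry
#'
#' An `image_grid` describes the sampling geometry of a 3D scalar field:
#' voxel counts per axis, voxel spacing in millimetres, and the world
#' coordinate (mm) of the centre of the first voxel. Voxel indices are
#' 0-based with axis order (x, y, z), z being the slice axis, so the world
#' position of voxel `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#'
#' @param shape integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel per axis (all > 0).
#' @param origin numeric vector of length 3, mm position of the first voxel
#'   centre. Defaults to the world origin.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 64), c(2, 2, 3))
#' voxel_volume_ml(g)
#' @export
image_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("shape, spacing and origin must each have length 3")
  if (any(!is.finite(shape)) || any(shape < 1L))
    stop("all shape components must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be > 0")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Physical extent of a grid in millimetres
#'
#' @param grid an [image_grid()].
#' @return Numeric length-3 vector, `shape * spacing` per axis (mm).
#' @export
grid_extent_mm <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  grid$shape * grid$spacing
}

#' Volume of one voxel in millilitres
#'
#' The product of the three spacings (mm^3) divided by 1000.
#'
#' @param grid an [image_grid()].
#' @return Millilitres per voxel (scalar).
#' @examples
#' voxel_volume_ml(image_grid(c(10, 10, 10), c(1.36, 1.36, 3)))
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  prod(grid$spacing) / 1000
}

#' World coordinates of voxel centres
#'
#' @param grid an [image_grid()].
#' @param index0 matrix (n x 3) of 0-based voxel indices, or a length-3 vector.
#' @return Matrix (n x 3) of mm positions.
#' @export
voxel_world_mm <- function(grid, index0) {
  stopifnot(inherits(grid, "image_grid"))
  if (is.null(dim(index0))) index0 <- matrix(index0, ncol = 3)
  sweep(sweep(index0, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

.modalities <- c("CT_HU", "PET_ACTIVITY", "PET_SUV", "NORMALIZED")

#' Scalar image volume
#'
#' A `volume` couples a 3D numeric array with an [image_grid()] and a modality
#' tag. CT volumes carry Hounsfield units, PET volumes activity concentration
#' (kBq/ml by default), `PET_SUV` dimensionless standardised uptake values and
#' `NORMALIZED` values in \[-1, 1\] as produced by [clamp_scale()].
#'
#' @param values 3D numeric array; its `dim` must equal `grid$shape`.
#' @param grid an [image_grid()].
#' @param modality one of `"CT_HU"`, `"PET_ACTIVITY"`, `"PET_SUV"`,
#'   `"NORMALIZED"`.
#' @param units free-text physical units of the stored values (e.g. `"HU"`,
#'   `"kBq/ml"`).
#' @return An object of class `volume`.
#' @export
volume <- function(values, grid, modality = "CT_HU",
                   units = c(CT_HU = "HU", PET_ACTIVITY = "kBq/ml",
                             PET_SUV = "SUV", NORMALIZED = "1")[[modality]]) {
  modality <- match.arg(modality, .modalities)
  stopifnot(inherits(grid, "image_grid"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("value array shape must equal grid shape")
  if (modality == "NORMALIZED") {
    rng <- range(values)
    if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
      stop("NORMALIZED volumes must have all values in [-1, 1]")
  }
  structure(list(values = values, grid = grid, modality = modality,
                 units = units), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("volume [%s]: %d x %d x %d, spacing (%g, %g, %g) mm, range [%g, %g] %s\n",
              x$modality, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$spacing[1], x$grid$spacing[2], x$grid$spacing[3],
              min(x$values), max(x$values), x$units))
  invisible(x)
}

#' Integer label map aligned to a grid
#'
#' Voxel values are non-negative registry indices, 0 meaning background.
#' Every nonzero value must resolve to an entry of the associated
#' [label_registry] (checked unless `check = FALSE`).
#'
#' @param labels 3D integer array with `dim` equal to `grid$shape`.
#' @param grid an [image_grid()].
#' @param registry a [label_registry] (or `NULL` to skip resolution checks).
#' @param check validate that nonzero labels resolve in the registry.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, grid, registry = NULL, check = !is.null(registry)) {
  stopifnot(inherits(grid, "image_grid"))
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label array shape must equal grid shape")
  if (any(labels < 0L)) stop("labels must be non-negative")
  if (check) {
    present <- setdiff(unique(as.vector(labels)), 0L)
    bad <- setdiff(present, registry$index)
    if (length(bad))
      stop("labels not resolvable in registry: ", paste(bad, collapse = ", "))
  }
  structure(list(labels = labels, grid = grid, registry = registry),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  nz <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("label_map: %d x %d x %d, %d distinct labels\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], length(nz)))
  invisible(x)
}

#' Per-study annotation mask
#'
#' Records which registry labels were actually annotated (verified) in a
#' study. Labels outside the annotated set contribute nothing to training
#' losses or evaluation metrics for that study; background (label 0) is
#' always considered annotated.
#'
#' @param annotated_labels integer vector of registry indices present/verified.
#' @param registry optional [label_registry] used to validate the indices.
#' @return An object of class `annotation_mask`.
#' @export
annotation_mask <- function(annotated_labels, registry = NULL) {
  annotated_labels <- sort(unique(as.integer(annotated_labels)))
  annotated_labels <- setdiff(annotated_labels, 0L)
  if (!is.null(registry)) {
    bad <- setdiff(annotated_labels, registry$index)
    if (length(bad))
      stop("annotated labels not in registry: ", paste(bad, collapse = ", "))
  }
  structure(list(annotated_labels = annotated_labels), class = "annotation_mask")
}

#' Voxelwise validity weights from an annotation mask
#'
#' @param annotation an [annotation_mask()], or `NULL` for fully annotated.
#' @param labels a [label_map()] or integer array of true labels.
#' @return Numeric array of 0/1 weights: 1 where the true label is background
#'   or annotated, 0 where the study lacks annotation for the true label.
#' @export
annotation_weights <- function(annotation, labels) {
  arr <- if (inherits(labels, "label_map")) labels$labels else labels
  if (is.null(annotation)) return(array(1, dim = dim(arr)))
  stopifnot(inherits(annotation, "annotation_mask"))
  w <- array(1, dim = dim(arr))
  w[!(arr %in% c(0L, annotation$annotated_labels))] <- 0
  w
}

# ---------------------------------------------------------------------------
# Label registry
# ---------------------------------------------------------------------------

.registry_version <- "orgseg-registry v1"

#' Build a label registry from an organ catalogue
#'
#' Expands catalogue rows (name, group, count, instance class) into one
#' registry entry per organ instance. Bilateral rows (`count == 2`) expand to
#' distinct left/right entries; vertebra rows expand to ordinal entries
#' (e.g. "Cervical vertebrae 1".."7"); the 24 ribs expand to "Rib left 1..12"
#' and "Rib right 1..12". Indices are assigned contiguously from 1 in
#' catalogue order.
#'
#' @param catalogue data frame with columns `name`, `singular`, `group`
#'   (`"bone"` or `"soft_tissue"`), `count` and `instance_class`
#'   (`"vertebra"`, `"rib"`, `"plain"`). Defaults to the shipped catalogue
#'   of 100 organs (77 bones and 23 soft-tissue organs).
#' @param require_full check that bone entries total 77 and soft-tissue
#'   entries total 23 (the canonical full catalogue).
#' @return A data frame of class `label_registry` with columns `index`,
#'   `name`, `group`, `instance_class`, `laterality`.
#' @examples
#' reg <- build_registry()
#' table(reg$group)
#' @export
build_registry <- function(catalogue = organ_catalogue(), require_full = FALSE) {
  need <- c("name", "singular", "group", "count", "instance_class")
  if (nrow(catalogue) == 0L) {
    reg <- data.frame(index = integer(), name = character(),
                      group = character(), instance_class = character(),
                      laterality = character(), stringsAsFactors = FALSE)
    class(reg) <- c("label_registry", "data.frame")
    attr(reg, "version") <- .registry_version
    return(reg)
  }
  if (!all(need %in% names(catalogue)))
    stop("catalogue must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(catalogue$name))
    stop("duplicate catalogue names: ",
         paste(unique(catalogue$name[duplicated(catalogue$name)]), collapse = ", "))
  if (!all(catalogue$group %in% c("bone", "soft_tissue")))
    stop("group must be 'bone' or 'soft_tissue'")
  if (!all(catalogue$instance_class %in% c("vertebra", "rib", "plain")))
    stop("instance_class must be 'vertebra', 'rib' or 'plain'")
  if (any(catalogue$count < 1L)) stop("counts must be >= 1")

  rows <- lapply(seq_len(nrow(catalogue)), function(i) {
    r <- catalogue[i, ]
    n <- as.integer(r$count)
    if (r$instance_class == "vertebra") {
      data.frame(name = paste(r$name, seq_len(n)), group = r$group,
                 instance_class = "vertebra", laterality = "none",
                 stringsAsFactors = FALSE)
    } else if (r$instance_class == "rib") {
      if (n %% 2L != 0L) stop("rib count must be even (left/right pairs)")
      k <- n %/% 2L
      data.frame(name = c(paste(r$singular, "left", seq_len(k)),
                          paste(r$singular, "right", seq_len(k))),
                 group = r$group, instance_class = "rib",
                 laterality = rep(c("left", "right"), each = k),
                 stringsAsFactors = FALSE)
    } else if (n == 1L) {
      data.frame(name = r$name, group = r$group, instance_class = "plain",
                 laterality = "none", stringsAsFactors = FALSE)
    } else if (n == 2L) {
      data.frame(name = paste(r$singular, c("left", "right")), group = r$group,
                 instance_class = "plain", laterality = c("left", "right"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = paste(r$singular, seq_len(n)), group = r$group,
                 instance_class = "plain", laterality = "none",
                 stringsAsFactors = FALSE)
    }
  })
  reg <- do.call(rbind, rows)
  if (anyDuplicated(reg$name))
    stop("duplicate expanded names: ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "))
  reg <- cbind(data.frame(index = seq_len(nrow(reg))), reg)
  if (require_full) {
    nb <- sum(reg$group == "bone"); ns <- sum(reg$group == "soft_tissue")
    if (nb != 77L || ns != 23L)
      stop(sprintf("full catalogue must expand to 77 bone and 23 soft-tissue entries, got %d/%d",
                   nb, ns))
  }
  class(reg) <- c("label_registry", "data.frame")
  attr(reg, "version") <- .registry_version
  rownames(reg) <- NULL
  reg
}

#' @export
print.label_registry <- function(x, ...) {
  cat(sprintf("label_registry (%s): %d entries (%d bone, %d soft tissue)\n",
              attr(x, "version"), nrow(x), sum(x$group == "bone"),
              sum(x$group == "soft_tissue")))
  invisible(x)
}

#' Read the shipped organ catalogue
#'
#' The catalogue lists the organs segmented by the platform grouped by type:
#' 77 bones and 23 soft-tissue organs in total, including multi-instance
#' entries (7 cervical, 12 thoracic and 5 lumbar vertebrae; 24 ribs).
#'
#' @param path path to a catalogue TSV; defaults to the file shipped with
#'   the package.
#' @return Data frame with columns `name`, `singular`, `group`, `count`,
#'   `instance_class`.
#' @export
organ_catalogue <- function(path = system.file("extdata", "organ_catalogue.tsv",
                                               package = "orgseg")) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

.registry_cache <- new.env(parent = emptyenv())

#' The canonical 100-organ registry
#'
#' Memoised expansion of the shipped catalogue; validated to contain exactly
#' 77 bone and 23 soft-tissue entries.
#'
#' @return A [label_registry].
#' @export
default_registry <- function() {
  if (is.null(.registry_cache$reg))
    .registry_cache$reg <- build_registry(organ_catalogue(), require_full = TRUE)
  .registry_cache$reg
}

#' Serialise / read a label registry as a plain-text table
#'
#' The on-disk format is a tab-separated table with a version header line;
#' `read_registry(write_registry(reg, f))` is an identity.
#'
#' @param registry a [label_registry].
#' @param path output (input) file path.
#' @return `write_registry` returns `path` invisibly; `read_registry` returns
#'   a [label_registry].
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "label_registry"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", attr(registry, "version")), con)
  utils::write.table(as.data.frame(registry), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  first <- readLines(path, n = 1L)
  version <- sub("^#\\s*", "", first)
  reg <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  reg$index <- as.integer(reg$index)
  if (!identical(reg$index, seq_len(nrow(reg))))
    stop("registry indices must be contiguous from 1")
  class(reg) <- c("label_registry", "data.frame")
  attr(reg, "version") <- version
  reg
}

#' Registry indices for an instance class
#'
#' @param registry a [label_registry].
#' @param class `"vertebra"` or `"rib"`.
#' @return Integer vector of registry indices in registry (cranio-caudal)
#'   order.
#' @export
registry_instance_indices <- function(registry, class = c("vertebra", "rib")) {
  class <- match.arg(class)
  registry$index[registry$instance_class == class]
}
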