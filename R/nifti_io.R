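# NIfTI-1 interchange via RNifti. The affine stored is a positive-diagonal
# sform (spacing on the diagonal, origin in the translation column) in the
# package's internal axis convention; no RAS/LPS reorientation is applied.

#' Write / read a volume as NIfTI
#'
#' @param vol a [volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param modality modality tag assigned on read.
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` a [volume()].
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  arr <- vol$values
  attr(arr, "pixdim") <- vol$grid$spacing
  attr(arr, "pixunits") <- c("mm", "s")
  img <- RNifti::asNifti(arr)
  xf <- rbind(cbind(diag(vol$grid$spacing), vol$grid$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, modality = "CT_HU") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(xf, "try-error")) xf[1:3, 4] else c(0, 0, 0)
  volume(arr, image_grid(dim(arr), spacing, origin), modality)
}

#' Write / read a label map as NIfTI
#'
#' Integer-valued NIfTI image; the round-trip reproduces the label array
#' exactly.
#'
#' @param labels a [label_map()].
#' @param path output path.
#' @param registry optional [label_registry] attached on read.
#' @return `write_labelmap_nifti` returns `path` invisibly;
#'   `read_labelmap_nifti` a [label_map()].
#' @export
write_labelmap_nifti <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  arr <- labels$labels
  attr(arr, "pixdim") <- labels$grid$spacing
  attr(arr, "pixunits") <- c("mm", "s")
  img <- RNifti::asNifti(arr, datatype = "int16")
  xf <- rbind(cbind(diag(labels$grid$spacing), labels$grid$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_labelmap_nifti
#' @export
read_labelmap_nifti <- function(path, registry = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  storage.mode(arr) <- "integer"
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(xf, "try-error")) xf[1:3, 4] else c(0, 0, 0)
  label_map(arr, image_grid(dim(arr), spacing, origin), registry, check = FALSE)
}
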