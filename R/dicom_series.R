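# DICOM series writers/readers for CT, PET and label (segmentation-style)
# objects. Geometry convention: Columns = x voxels, Rows = y voxels,
# PixelSpacing = (row spacing = y, column spacing = x), slices along +z.

.sop_ct <- "1.2.840.10008.5.1.4.1.1.2"
.sop_pt <- "1.2.840.10008.5.1.4.1.1.128"
.sop_seg <- "1.2.840.10008.5.1.4.1.1.66.4"

.dcm_geometry_elements <- function(grid, k) {
  pos <- grid$origin + c(0, 0, (k - 1L) * grid$spacing[3])
  list(dcm_element("PixelSpacing", c(grid$spacing[2], grid$spacing[1])),
       dcm_element("SliceThickness", grid$spacing[3]),
       dcm_element("SpacingBetweenSlices", grid$spacing[3]),
       dcm_element("ImagePositionPatient", pos),
       dcm_element("ImageOrientationPatient", c(1, 0, 0, 0, 1, 0)),
       dcm_element("Rows", grid$shape[2]),
       dcm_element("Columns", grid$shape[1]),
       dcm_element("SamplesPerPixel", 1L),
       dcm_element("PhotometricInterpretation", "MONOCHROME2"))
}

.default_patient <- function() {
  list(name = "PHANTOM^TEST", id = "PHANTOM001", birth_date = "19700101",
       sex = "O", weight_kg = 70)
}

#' Write a CT volume as a DICOM series
#'
#' One file per slice, explicit VR little endian, stored values rescaled to
#' HU with slope 1 and intercept -1024 (HU quantised to integers).
#'
#' @param vol a `CT_HU` [volume()].
#' @param dir output directory (created).
#' @param patient list with `name`, `id`, `birth_date`, `sex` and optional
#'   extra identifying fields used by the de-identification tests.
#' @param study_uid,series_uid UIDs (generated when `NULL`).
#' @return The output directory, invisibly.
#' @export
write_ct_dicom <- function(vol, dir, patient = .default_patient(),
                           study_uid = NULL, series_uid = NULL) {
  stopifnot(inherits(vol, "volume"))
  if (vol$modality != "CT_HU") stop("write_ct_dicom expects a CT_HU volume")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study_uid <- study_uid %||% dcm_new_uid()
  series_uid <- series_uid %||% dcm_new_uid()
  frame_uid <- dcm_new_uid()
  g <- vol$grid
  stored <- round(vol$values) + 1024
  if (any(stored < 0 | stored > 65535))
    stop("HU values outside the encodable range [-1024, 64511]")
  for (k in seq_len(g$shape[3])) {
    px <- writeBin(as.integer(stored[, , k]), raw(), size = 2, endian = "little")
    ds <- c(list(
      dcm_element("SOPClassUID", .sop_ct),
      dcm_element("SOPInstanceUID", dcm_new_uid()),
      dcm_element("Modality", "CT"),
      dcm_element("StudyDate", "20240102"),
      dcm_element("StudyTime", "101500"),
      dcm_element("AccessionNumber", "ACC123456"),
      dcm_element("InstitutionName", "General Hospital Alpha"),
      dcm_element("ReferringPhysicianName", "REFERRER^DOC"),
      dcm_element("PatientName", patient$name),
      dcm_element("PatientID", patient$id),
      dcm_element("PatientBirthDate", patient$birth_date),
      dcm_element("PatientSex", patient$sex),
      dcm_element("StudyInstanceUID", study_uid),
      dcm_element("SeriesInstanceUID", series_uid),
      dcm_element("FrameOfReferenceUID", frame_uid),
      dcm_element("SeriesNumber", 1L),
      dcm_element("InstanceNumber", k),
      dcm_element("BitsAllocated", 16L),
      dcm_element("BitsStored", 16L),
      dcm_element("HighBit", 15L),
      dcm_element("PixelRepresentation", 0L),
      dcm_element("RescaleSlope", 1),
      dcm_element("RescaleIntercept", -1024),
      dcm_element("PixelData", px)),
      .dcm_geometry_elements(g, k))
    dicom_write(ds, file.path(dir, sprintf("ct_%04d.dcm", k)))
  }
  invisible(dir)
}

.read_series_datasets <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no DICOM files in ", path)
  dss <- lapply(files, dicom_read)
  series <- vapply(dss, function(d) dcm_get(d, "SeriesInstanceUID"), character(1))
  if (length(unique(series)) != 1L)
    stop("directory contains a mixed series")
  z <- vapply(dss, function(d) {
    ipp <- dcm_get(d, "ImagePositionPatient")
    if (is.null(ipp)) stop("missing ImagePositionPatient")
    ipp[3]
  }, numeric(1))
  dss[order(z)]
}

.series_grid <- function(dss) {
  d1 <- dss[[1]]
  ps <- dcm_get(d1, "PixelSpacing")
  if (is.null(ps)) stop("missing PixelSpacing")
  nx <- dcm_get(d1, "Columns"); ny <- dcm_get(d1, "Rows")
  z <- vapply(dss, function(d) dcm_get(d, "ImagePositionPatient")[3], numeric(1))
  dz <- if (length(z) > 1L) mean(diff(z)) else
    (dcm_get(d1, "SpacingBetweenSlices") %||% dcm_get(d1, "SliceThickness") %||% 1)
  origin <- dcm_get(d1, "ImagePositionPatient")
  image_grid(c(nx, ny, length(dss)), c(ps[2], ps[1], dz), origin)
}

#' Read a CT DICOM series into a volume
#'
#' Slices are sorted by their z position (file order is irrelevant) and
#' stored values rescaled to HU via the slope/intercept tags.
#'
#' @param path directory containing one CT series.
#' @return A `CT_HU` [volume()].
#' @export
read_ct_series <- function(path) {
  dss <- .read_series_datasets(path)
  grid <- .series_grid(dss)
  arr <- array(0, grid$shape)
  for (k in seq_along(dss)) {
    d <- dss[[k]]
    px <- dcm_get(d, "PixelData")
    stored <- readBin(px, "integer", n = length(px) / 2, size = 2,
                      signed = FALSE, endian = "little")
    slope <- dcm_get(d, "RescaleSlope") %||% 1
    inter <- dcm_get(d, "RescaleIntercept") %||% 0
    arr[, , k] <- array(stored * slope + inter, grid$shape[1:2])
  }
  volume(arr, grid, "CT_HU")
}

#' Write a PET volume as a DICOM series
#'
#' Activity concentration is stored as 32-bit floats (FloatPixelData) in
#' Bq/ml so write/read round-trips are exact to float precision, together
#' with the radiopharmaceutical information (injected dose, injection time,
#' half-life) and patient weight needed for SUV computation.
#'
#' @param pet a `PET_ACTIVITY` [volume()] (kBq/ml).
#' @param dir output directory.
#' @param context an [suv_context()].
#' @param patient patient metadata list (see [write_ct_dicom()]).
#' @param scan_time series acquisition time (`"HHMMSS"`); together with the
#'   injection time it determines the decay interval.
#' @return The output directory, invisibly.
#' @export
write_pet_dicom <- function(pet, dir, context, patient = .default_patient(),
                            scan_time = "110000") {
  stopifnot(inherits(pet, "volume"), inherits(context, "suv_context"))
  if (pet$modality != "PET_ACTIVITY") stop("write_pet_dicom expects PET_ACTIVITY")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series_uid <- dcm_new_uid(); study_uid <- dcm_new_uid()
  g <- pet$grid
  inj_time <- .seconds_to_tm(.tm_to_seconds(scan_time) - context$elapsed_s)
  for (k in seq_len(g$shape[3])) {
    px <- writeBin(as.numeric(pet$values[, , k] * 1000), raw(), size = 4,
                   endian = "little")
    rph <- list(list(dcm_element("RadionuclideTotalDose", context$dose_bq),
                     dcm_element("RadionuclideHalfLife", context$half_life_s),
                     dcm_element("RadiopharmaceuticalStartTime", inj_time)))
    ds <- c(list(
      dcm_element("SOPClassUID", .sop_pt),
      dcm_element("SOPInstanceUID", dcm_new_uid()),
      dcm_element("Modality", "PT"),
      dcm_element("Units", "BQML"),
      dcm_element("AcquisitionTime", scan_time),
      dcm_element("SeriesTime", scan_time),
      dcm_element("PatientName", patient$name),
      dcm_element("PatientID", patient$id),
      dcm_element("PatientWeight", context$weight_kg),
      dcm_element("StudyInstanceUID", study_uid),
      dcm_element("SeriesInstanceUID", series_uid),
      dcm_element("SeriesNumber", 2L),
      dcm_element("InstanceNumber", k),
      dcm_element("BitsAllocated", 32L),
      dcm_element("RadiopharmaceuticalInformationSequence", rph),
      dcm_element("FloatPixelData", px)),
      .dcm_geometry_elements(g, k))
    dicom_write(ds, file.path(dir, sprintf("pt_%04d.dcm", k)))
  }
  invisible(dir)
}

.tm_to_seconds <- function(tm) {
  h <- as.numeric(substr(tm, 1, 2)); m <- as.numeric(substr(tm, 3, 4))
  s <- as.numeric(substring(tm, 5))
  if (is.na(s)) s <- 0
  h * 3600 + m * 60 + s
}

.seconds_to_tm <- function(sec) {
  sec <- max(0, sec)
  sprintf("%02d%02d%02d", floor(sec / 3600), floor((sec %% 3600) / 60),
          round(sec %% 60))
}

#' Read a PET DICOM series
#'
#' @param path directory containing one PET series.
#' @return A list with `volume` (a `PET_ACTIVITY` [volume()], kBq/ml) and
#'   `context` (an [suv_context()] reconstructed from the
#'   radiopharmaceutical tags, or `NULL` when they are absent).
#' @export
read_pet_series <- function(path) {
  dss <- .read_series_datasets(path)
  grid <- .series_grid(dss)
  arr <- array(0, grid$shape)
  for (k in seq_along(dss)) {
    px <- dcm_get(dss[[k]], "FloatPixelData")
    arr[, , k] <- array(readBin(px, "double", n = length(px) / 4, size = 4,
                                endian = "little") / 1000, grid$shape[1:2])
  }
  d1 <- dss[[1]]
  ctx <- NULL
  rph <- dcm_get(d1, "RadiopharmaceuticalInformationSequence")
  wt <- dcm_get(d1, "PatientWeight")
  if (!is.null(rph) && length(rph) && !is.null(wt)) {
    item <- rph[[1]]
    dose <- dcm_get(item, "RadionuclideTotalDose")
    hl <- dcm_get(item, "RadionuclideHalfLife")
    inj <- dcm_get(item, "RadiopharmaceuticalStartTime")
    scan <- dcm_get(d1, "SeriesTime") %||% dcm_get(d1, "AcquisitionTime")
    if (!is.null(dose) && !is.null(hl)) {
      elapsed <- if (!is.null(inj) && !is.null(scan))
        max(0, .tm_to_seconds(scan) - .tm_to_seconds(inj)) else 0
      ctx <- suv_context(dose, hl, wt, elapsed)
    }
  } else {
    warning("PET series lacks dose or weight; SUV context unavailable")
  }
  list(volume = volume(arr, grid, "PET_ACTIVITY"), context = ctx)
}

#' Write a label map as a segmentation-style DICOM object
#'
#' A single multiframe file under the Segmentation SOP class: label indices
#' as unsigned 16-bit PixelData (one frame per slice) and a SegmentSequence
#' item per label carrying SegmentNumber and SegmentLabel, so the label
#' array and label names round-trip exactly.
#'
#' @param labels a [label_map()].
#' @param registry a [label_registry] resolving label names (only labels
#'   present in the map are encoded; `NULL` uses `"label-<k>"` names).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labelmap_dicom <- function(labels, registry = NULL, path) {
  stopifnot(inherits(labels, "label_map"))
  g <- labels$grid
  if (max(labels$labels) > 65535L) stop("labels exceed the encodable range")
  present <- sort(setdiff(unique(as.vector(labels$labels)), 0L))
  segs <- lapply(present, function(k) {
    nm <- if (!is.null(registry)) registry$name[match(k, registry$index)]
    else sprintf("label-%d", k)
    list(dcm_element("SegmentNumber", k), dcm_element("SegmentLabel", nm))
  })
  px <- writeBin(as.integer(labels$labels), raw(), size = 2, endian = "little")
  ds <- c(list(
    dcm_element("SOPClassUID", .sop_seg),
    dcm_element("SOPInstanceUID", dcm_new_uid()),
    dcm_element("Modality", "SEG"),
    dcm_element("SeriesInstanceUID", dcm_new_uid()),
    dcm_element("StudyInstanceUID", dcm_new_uid()),
    dcm_element("NumberOfFrames", g$shape[3]),
    dcm_element("BitsAllocated", 16L),
    dcm_element("BitsStored", 16L),
    dcm_element("HighBit", 15L),
    dcm_element("PixelRepresentation", 0L),
    dcm_element("SegmentSequence", segs),
    dcm_element("PixelData", px)),
    .dcm_geometry_elements(g, 1L))
  dicom_write(ds, path)
  invisible(path)
}

#' Read a segmentation-style DICOM label object
#'
#' @param path file written by [write_labelmap_dicom()].
#' @param registry optional [label_registry] attached to the result.
#' @return A [label_map()] with a `segment_labels` attribute (named
#'   character vector: names are label indices).
#' @export
read_labelmap_dicom <- function(path, registry = NULL) {
  ds <- dicom_read(path)
  nx <- dcm_get(ds, "Columns"); ny <- dcm_get(ds, "Rows")
  nz <- dcm_get(ds, "NumberOfFrames")
  ps <- dcm_get(ds, "PixelSpacing")
  dz <- dcm_get(ds, "SpacingBetweenSlices") %||% dcm_get(ds, "SliceThickness") %||% 1
  origin <- dcm_get(ds, "ImagePositionPatient") %||% c(0, 0, 0)
  grid <- image_grid(c(nx, ny, nz), c(ps[2], ps[1], dz), origin)
  px <- dcm_get(ds, "PixelData")
  lab <- array(readBin(px, "integer", n = length(px) / 2, size = 2,
                       signed = FALSE, endian = "little"), grid$shape)
  segs <- dcm_get(ds, "SegmentSequence") %||% list()
  nm <- vapply(segs, function(s) as.character(dcm_get(s, "SegmentLabel")), character(1))
  names(nm) <- vapply(segs, function(s) as.character(dcm_get(s, "SegmentNumber")), character(1))
  out <- label_map(lab, grid, registry, check = FALSE)
  attr(out, "segment_labels") <- nm
  out
}
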