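# Minimal DICOM codec: explicit VR little endian read/write of the attribute
# subset the package needs (CT/PT image slices, a segmentation-style label
# object, and the de-identification profile attributes). No installed R
# package provides DICOM I/O, so the codec lives here. Datasets are
# represented as lists of elements `list(group, element, vr, value)`;
# sequence (SQ) values are lists of such datasets.

.dcm_dict <- local({
  d <- list(
    FileMetaInformationGroupLength = c(0x0002, 0x0000, "UL"),
    MediaStorageSOPClassUID        = c(0x0002, 0x0002, "UI"),
    MediaStorageSOPInstanceUID     = c(0x0002, 0x0003, "UI"),
    TransferSyntaxUID              = c(0x0002, 0x0010, "UI"),
    ImplementationClassUID         = c(0x0002, 0x0012, "UI"),
    SpecificCharacterSet   = c(0x0008, 0x0005, "CS"),
    SOPClassUID            = c(0x0008, 0x0016, "UI"),
    SOPInstanceUID         = c(0x0008, 0x0018, "UI"),
    StudyDate              = c(0x0008, 0x0020, "DA"),
    SeriesDate             = c(0x0008, 0x0021, "DA"),
    AcquisitionDate        = c(0x0008, 0x0022, "DA"),
    ContentDate            = c(0x0008, 0x0023, "DA"),
    StudyTime              = c(0x0008, 0x0030, "TM"),
    SeriesTime             = c(0x0008, 0x0031, "TM"),
    AcquisitionTime        = c(0x0008, 0x0032, "TM"),
    AccessionNumber        = c(0x0008, 0x0050, "SH"),
    Modality               = c(0x0008, 0x0060, "CS"),
    Manufacturer           = c(0x0008, 0x0070, "LO"),
    InstitutionName        = c(0x0008, 0x0080, "LO"),
    InstitutionAddress     = c(0x0008, 0x0081, "ST"),
    ReferringPhysicianName = c(0x0008, 0x0090, "PN"),
    StationName            = c(0x0008, 0x1010, "SH"),
    SeriesDescription      = c(0x0008, 0x103E, "LO"),
    PerformingPhysicianName = c(0x0008, 0x1050, "PN"),
    OperatorsName          = c(0x0008, 0x1070, "PN"),
    PatientName            = c(0x0010, 0x0010, "PN"),
    PatientID              = c(0x0010, 0x0020, "LO"),
    PatientBirthDate       = c(0x0010, 0x0030, "DA"),
    PatientSex             = c(0x0010, 0x0040, "CS"),
    OtherPatientIDs        = c(0x0010, 0x1000, "LO"),
    PatientAge             = c(0x0010, 0x1010, "AS"),
    PatientWeight          = c(0x0010, 0x1030, "DS"),
    PatientAddress         = c(0x0010, 0x1040, "LO"),
    PatientTelephoneNumbers = c(0x0010, 0x2154, "SH"),
    DeviceSerialNumber     = c(0x0018, 0x1000, "LO"),
    SliceThickness         = c(0x0018, 0x0050, "DS"),
    SpacingBetweenSlices   = c(0x0018, 0x0088, "DS"),
    RadiopharmaceuticalStartTime = c(0x0018, 0x1072, "TM"),
    RadionuclideTotalDose  = c(0x0018, 0x1074, "DS"),
    RadionuclideHalfLife   = c(0x0018, 0x1075, "DS"),
    StudyInstanceUID       = c(0x0020, 0x000D, "UI"),
    SeriesInstanceUID      = c(0x0020, 0x000E, "UI"),
    StudyID                = c(0x0020, 0x0010, "SH"),
    SeriesNumber           = c(0x0020, 0x0011, "IS"),
    InstanceNumber         = c(0x0020, 0x0013, "IS"),
    ImagePositionPatient   = c(0x0020, 0x0032, "DS"),
    ImageOrientationPatient = c(0x0020, 0x0037, "DS"),
    FrameOfReferenceUID    = c(0x0020, 0x0052, "UI"),
    SamplesPerPixel        = c(0x0028, 0x0002, "US"),
    PhotometricInterpretation = c(0x0028, 0x0004, "CS"),
    NumberOfFrames         = c(0x0028, 0x0008, "IS"),
    Rows                   = c(0x0028, 0x0010, "US"),
    Columns                = c(0x0028, 0x0011, "US"),
    PixelSpacing           = c(0x0028, 0x0030, "DS"),
    BitsAllocated          = c(0x0028, 0x0100, "US"),
    BitsStored             = c(0x0028, 0x0101, "US"),
    HighBit                = c(0x0028, 0x0102, "US"),
    PixelRepresentation    = c(0x0028, 0x0103, "US"),
    RescaleIntercept       = c(0x0028, 0x1052, "DS"),
    RescaleSlope           = c(0x0028, 0x1053, "DS"),
    RadiopharmaceuticalInformationSequence = c(0x0054, 0x0016, "SQ"),
    Units                  = c(0x0054, 0x1001, "CS"),
    SegmentSequence        = c(0x0062, 0x0002, "SQ"),
    SegmentNumber          = c(0x0062, 0x0004, "US"),
    SegmentLabel           = c(0x0062, 0x0005, "LO"),
    FloatPixelData         = c(0x7FE0, 0x0008, "OF"),
    PixelData              = c(0x7FE0, 0x0010, "OW"))
  d
})

.dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                     "PN", "SH", "ST", "TM", "UI", "UT")
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Construct a DICOM element by attribute name
#'
#' @param name attribute keyword from the package's tag dictionary.
#' @param value element value: character or numeric vector (multi-values
#'   allowed), a raw vector for pixel-data VRs, or a list of datasets for
#'   sequences.
#' @return A DICOM element (list with `group`, `element`, `vr`, `value`).
#' @export
dcm_element <- function(name, value) {
  e <- .dcm_dict[[name]]
  if (is.null(e)) stop("unknown DICOM attribute: ", name)
  list(group = as.integer(e[1]), element = as.integer(e[2]), vr = e[3],
       value = value, name = name)
}

.dcm_tag_name <- local({
  tags <- vapply(.dcm_dict, function(e)
    sprintf("%04X,%04X", as.integer(e[1]), as.integer(e[2])), character(1))
  function(group, element) {
    key <- sprintf("%04X,%04X", group, element)
    i <- match(key, tags)
    if (is.na(i)) NA_character_ else names(.dcm_dict)[i]
  }
})

#' Look up an element value in a dataset
#'
#' @param ds a dataset (list of elements) as returned by [dicom_read()].
#' @param name attribute keyword.
#' @return The element value, or `NULL` when absent.
#' @export
dcm_get <- function(ds, name) {
  e <- .dcm_dict[[name]]
  if (is.null(e)) stop("unknown DICOM attribute: ", name)
  for (el in ds)
    if (el$group == as.integer(e[1]) && el$element == as.integer(e[2]))
      return(el$value)
  NULL
}

.dcm_format_number <- function(x) {
  s <- formatC(x, format = "g", digits = 10, width = 1)
  gsub(" ", "", s)
}

.dcm_encode_value <- function(vr, value) {
  if (vr %in% .dcm_string_vrs) {
    if (is.numeric(value)) value <- .dcm_format_number(value)
    s <- paste(value, collapse = "\\")
    b <- charToRaw(enc2utf8(s))
    if (length(b) %% 2L == 1L)
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    b
  } else if (vr %in% c("US", "SS")) {
    writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr %in% c("UL", "SL")) {
    writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "FL" || vr == "OF") {
    if (is.raw(value)) value else
      writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    if (!is.raw(value)) stop("OB/OW values must be raw")
    value
  } else if (vr == "SQ") {
    items <- lapply(value, function(item_ds) {
      body <- .dcm_encode_dataset(item_ds)
      c(writeBin(c(0xFFFEL, 0xE000L), raw(), size = 2, endian = "little"),
        writeBin(length(body), raw(), size = 4, endian = "little"),
        body)
    })
    do.call(c, items)
  } else stop("unsupported VR: ", vr)
}

.dcm_encode_element <- function(el) {
  body <- .dcm_encode_value(el$vr, el$value)
  head <- c(writeBin(c(el$group, el$element), raw(), size = 2, endian = "little"),
            charToRaw(el$vr))
  if (el$vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  } else {
    if (length(body) > 65535L) stop("value too long for short-form VR ", el$vr)
    c(head, writeBin(length(body), raw(), size = 2, endian = "little"), body)
  }
}

.dcm_encode_dataset <- function(ds) {
  ord <- order(vapply(ds, function(e) e$group * 2^16 + e$element, numeric(1)))
  do.call(c, lapply(ds[ord], .dcm_encode_element))
}

.orgseg_uid_root <- "2.25."

#' Generate a DICOM UID
#'
#' UIDs under the UUID-derived root `2.25.`, drawn from the R session RNG.
#'
#' @param n number of UIDs.
#' @return Character vector of UIDs.
#' @export
dcm_new_uid <- function(n = 1L) {
  vapply(seq_len(n), function(i)
    paste0(.orgseg_uid_root,
           paste(sample(0:9, 30, replace = TRUE), collapse = "")),
    character(1))
}

#' Write a dataset as a DICOM Part-10 file
#'
#' Explicit VR little endian with a standard 128-byte preamble and file
#' meta group derived from the dataset's SOP class/instance UIDs.
#'
#' @param ds dataset: list of elements from [dcm_element()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
dicom_write <- function(ds, path) {
  sop_class <- dcm_get(ds, "SOPClassUID") %||% "1.2.840.10008.5.1.4.1.1.2"
  sop_inst <- dcm_get(ds, "SOPInstanceUID") %||% dcm_new_uid()
  meta <- list(
    dcm_element("MediaStorageSOPClassUID", sop_class),
    dcm_element("MediaStorageSOPInstanceUID", sop_inst),
    dcm_element("TransferSyntaxUID", "1.2.840.10008.1.2.1"),
    dcm_element("ImplementationClassUID", paste0(.orgseg_uid_root, "844902975207")))
  meta_body <- .dcm_encode_dataset(meta)
  meta_all <- c(.dcm_encode_element(dcm_element("FileMetaInformationGroupLength",
                                                length(meta_body))),
                meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta_all, con)
  writeBin(.dcm_encode_dataset(ds), con)
  invisible(path)
}

.dcm_decode_value <- function(vr, b) {
  if (vr %in% .dcm_string_vrs) {
    s <- rawToChar(b[b != as.raw(0)])
    s <- sub("\\s+$", "", s)
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (vr %in% c("DS", "IS")) as.numeric(parts) else parts
  } else if (vr == "US") {
    readBin(b, "integer", n = length(b) / 2, size = 2, signed = FALSE,
            endian = "little")
  } else if (vr == "SS") {
    readBin(b, "integer", n = length(b) / 2, size = 2, signed = TRUE,
            endian = "little")
  } else if (vr %in% c("UL", "SL")) {
    readBin(b, "integer", n = length(b) / 4, size = 4, endian = "little")
  } else if (vr == "FL") {
    readBin(b, "double", n = length(b) / 4, size = 4, endian = "little")
  } else if (vr == "FD") {
    readBin(b, "double", n = length(b) / 8, size = 8, endian = "little")
  } else {
    b  # OB / OW / OF and anything unrecognised stay raw
  }
}

.dcm_parse_dataset <- function(b, pos = 1L, end = length(b)) {
  u16 <- function(p) readBin(b[p:(p + 1L)], "integer", size = 2, signed = FALSE,
                             endian = "little")
  u32 <- function(p) readBin(b[p:(p + 3L)], "integer", size = 4,
                             endian = "little")
  ds <- list()
  while (pos + 7L <= end + 1L && pos <= end) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(b[(pos + 4L):(pos + 5L)])
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vstart <- pos + 8L
    }
    if (len < 0L) stop("undefined-length elements are not supported")
    vb <- if (len > 0L) b[vstart:(vstart + len - 1L)] else raw()
    value <- if (vr == "SQ") {
      items <- list()
      ip <- 1L
      while (ip + 7L <= len) {
        ig <- readBin(vb[ip:(ip + 1L)], "integer", size = 2, signed = FALSE,
                      endian = "little")
        ie <- readBin(vb[(ip + 2L):(ip + 3L)], "integer", size = 2,
                      signed = FALSE, endian = "little")
        il <- readBin(vb[(ip + 4L):(ip + 7L)], "integer", size = 4,
                      endian = "little")
        if (ig != 0xFFFE || ie != 0xE000) stop("malformed sequence item")
        items[[length(items) + 1L]] <-
          .dcm_parse_dataset(vb, ip + 8L, ip + 7L + il)
        ip <- ip + 8L + il
      }
      items
    } else {
      .dcm_decode_value(vr, vb)
    }
    ds[[length(ds) + 1L]] <- list(group = group, element = element, vr = vr,
                                  value = value,
                                  name = .dcm_tag_name(group, element))
    pos <- vstart + len
  }
  ds
}

#' Read a DICOM Part-10 file
#'
#' Supports the explicit VR little endian transfer syntax (the one the
#' package writes). File meta elements (group 0002) are dropped from the
#' returned dataset.
#'
#' @param path file path.
#' @return A dataset: list of elements with fields `group`, `element`,
#'   `vr`, `value`, `name`.
#' @export
dicom_read <- function(path) {
  b <- readBin(path, "raw", n = file.info(path)$size)
  if (length(b) < 134L || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  ds <- .dcm_parse_dataset(b, 133L)
  Filter(function(e) e$group != 0x0002, ds)
}
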