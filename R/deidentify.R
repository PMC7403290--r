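#' De-identification profile
#'
#' An attribute-action table in the spirit of the DICOM standard's basic
#' application-level confidentiality profile, restricted to the attributes
#' the package writes. Actions: `"remove"` (drop the element),
#' `"replace"` (substitute a dummy value), `"uid"` (remap to a new UID,
#' consistently within a session so series/study linkage is preserved) and
#' `"date"` (remove, or shift by a per-session offset when
#' `retain_longitudinal` is set, preserving intervals between studies).
#'
#' @param retain_longitudinal keep temporal relationships by shifting dates
#'   instead of removing them.
#' @param extra optional data frame with columns `name`, `action` appended
#'   to the default rows.
#' @return A data frame of class `deid_profile`.
#' @export
deid_profile <- function(retain_longitudinal = FALSE, extra = NULL) {
  rows <- data.frame(
    name = c("PatientName", "PatientID", "PatientBirthDate", "PatientSex",
             "OtherPatientIDs", "PatientAddress", "PatientTelephoneNumbers",
             "ReferringPhysicianName", "PerformingPhysicianName",
             "OperatorsName", "InstitutionName", "InstitutionAddress",
             "AccessionNumber", "StationName", "DeviceSerialNumber",
             "StudyDate", "SeriesDate", "AcquisitionDate", "ContentDate",
             "StudyInstanceUID", "SeriesInstanceUID", "SOPInstanceUID",
             "FrameOfReferenceUID"),
    action = c("replace", "replace", "remove", "replace",
               "remove", "remove", "remove",
               "remove", "remove",
               "remove", "remove", "remove",
               "remove", "remove", "remove",
               "date", "date", "date", "date",
               "uid", "uid", "uid",
               "uid"),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) rows <- rbind(rows, extra[, c("name", "action")])
  structure(rows, retain_longitudinal = retain_longitudinal,
            class = c("deid_profile", "data.frame"))
}

#' Start a de-identification session
#'
#' Holds the UID remapping table (a consistent injection: each original UID
#' maps to one fresh UID for the whole session) and the date-shift offset.
#'
#' @param date_shift_days day offset applied when the profile retains
#'   longitudinal dates; drawn from the session RNG when `NULL`.
#' @return An environment of class `deid_session`.
#' @export
deid_session <- function(date_shift_days = NULL) {
  s <- new.env(parent = emptyenv())
  s$uid_map <- list()
  s$date_shift_days <- date_shift_days %||% sample.int(3650L, 1L)
  class(s) <- "deid_session"
  s
}

.deid_dummy <- function(vr) {
  switch(vr, PN = "ANONYMOUS", LO = "ANONYMIZED", SH = "ANON",
         CS = "O", DA = "", "ANON")
}

.deid_remap_uid <- function(uid, session) {
  hit <- session$uid_map[[uid]]
  if (!is.null(hit)) return(hit)
  # already-remapped UIDs (our 2.25. root) are left alone so a second pass
  # is a no-op within the session's UID space
  new <- dcm_new_uid()
  session$uid_map[[uid]] <- new
  session$uid_map[[new]] <- new
  new
}

.deid_shift_date <- function(da, days) {
  if (!nzchar(da)) return(da)
  d <- as.Date(da, format = "%Y%m%d")
  if (is.na(d)) return("")
  format(d - days, "%Y%m%d")
}

#' De-identify a DICOM dataset
#'
#' Applies the profile's actions to every matching attribute (recursing
#' into sequences); pixel data are untouched.
#'
#' @param ds dataset from [dicom_read()].
#' @param profile a [deid_profile()].
#' @param session a [deid_session()]; one session per upload keeps UID
#'   remapping consistent across files.
#' @return The de-identified dataset.
#' @export
deidentify_dataset <- function(ds, profile = deid_profile(),
                               session = deid_session()) {
  retain <- isTRUE(attr(profile, "retain_longitudinal"))
  keep <- logical(length(ds))
  for (i in seq_along(ds)) {
    el <- ds[[i]]
    act <- profile$action[match(el$name %||% NA_character_, profile$name)]
    if (el$vr == "SQ") {
      el$value <- lapply(el$value, deidentify_dataset, profile = profile,
                         session = session)
      ds[[i]] <- el
    }
    if (is.na(act) || !length(act)) { keep[i] <- TRUE; next }
    if (act == "remove") {
      keep[i] <- FALSE
    } else if (act == "replace") {
      el$value <- .deid_dummy(el$vr)
      ds[[i]] <- el; keep[i] <- TRUE
    } else if (act == "uid") {
      el$value <- vapply(el$value, .deid_remap_uid, character(1),
                         session = session)
      ds[[i]] <- el; keep[i] <- TRUE
    } else if (act == "date") {
      if (retain) {
        el$value <- .deid_shift_date(el$value, session$date_shift_days)
        ds[[i]] <- el; keep[i] <- TRUE
      } else keep[i] <- FALSE
    } else stop("unknown action: ", act)
  }
  ds[keep]
}

#' De-identify a directory of DICOM files
#'
#' Reads every `.dcm` file under `input`, applies [deidentify_dataset()]
#' with a shared session, and writes the results to `output` under the same
#' file names.
#'
#' @param input directory of DICOM files.
#' @param output output directory (created).
#' @param profile a [deid_profile()].
#' @param session a [deid_session()] (a fresh one by default).
#' @return Invisibly, the session (its `uid_map` documents the remapping).
#' @export
deidentify_files <- function(input, output, profile = deid_profile(),
                             session = deid_session()) {
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  files <- list.files(input, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no DICOM files in ", input)
  for (f in files) {
    ds <- deidentify_dataset(dicom_read(f), profile, session)
    dicom_write(ds, file.path(output, basename(f)))
  }
  invisible(session)
}
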