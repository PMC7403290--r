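test_that("CT DICOM series round-trips HU values, spacing and origin", {
  tr <- tiny_phantom(noise_sd = 0)          # integer HU by construction
  d <- file.path(tempdir(), "ct_series")
  unlink(d, recursive = TRUE)
  set.seed(1)
  write_ct_dicom(tr$ct, d)
  back <- read_ct_series(d)
  expect_identical(dim(back$values), dim(tr$ct$values))
  expect_equal(back$values, tr$ct$values)     # bit-exact for integer HU
  expect_equal(back$grid$spacing, tr$ct$grid$spacing)
  expect_equal(back$grid$origin, tr$ct$grid$origin)
})

test_that("slice order on disk does not matter and rescale tags are honoured", {
  tr <- tiny_phantom(noise_sd = 0)
  d <- file.path(tempdir(), "ct_shuffle")
  unlink(d, recursive = TRUE)
  set.seed(2)
  write_ct_dicom(tr$ct, d)
  # shuffle file names so directory order disagrees with slice position
  files <- list.files(d, full.names = TRUE)
  set.seed(3)
  tmp <- file.path(d, paste0("zz_", sample(length(files)), ".dcm"))
  file.rename(files, tmp)
  back <- read_ct_series(d)
  expect_equal(back$values, tr$ct$values)

  # slope/intercept arithmetic: stored 1024 with intercept -1024 reads as 0 HU
  one <- dicom_read(list.files(d, full.names = TRUE)[1])
  expect_equal(dcm_get(one, "RescaleIntercept"), -1024)
  stored <- readBin(dcm_get(one, "PixelData"), "integer", n = 1, size = 2,
                    signed = FALSE, endian = "little")
  hu <- back$values[1, 1, which.min(vapply(
    list.files(d, full.names = TRUE), function(f)
      dcm_get(dicom_read(f), "ImagePositionPatient")[3], numeric(1)))]
  expect_equal(hu, stored * 1 - 1024)
})

test_that("PET DICOM series round-trips activity and radiopharmaceutical context", {
  tr <- tiny_phantom(noise_sd = 0)
  pet <- generate_pet(tr, c(`1` = 5.25, `2` = 1.5), noise_sd = 0.25, seed = 5)
  ctx <- suv_context(dose_bq = 1e8, half_life_s = 6586.2, weight_kg = 70,
                     elapsed_s = 1800)
  d <- file.path(tempdir(), "pt_series")
  unlink(d, recursive = TRUE)
  set.seed(4)
  write_pet_dicom(pet, d, ctx)
  back <- read_pet_series(d)
  # float32 storage: relative error at single precision
  expect_equal(back$volume$values, pet$values, tolerance = 1e-6)
  expect_equal(back$context$dose_bq, ctx$dose_bq)
  expect_equal(back$context$half_life_s, ctx$half_life_s)
  expect_equal(back$context$weight_kg, ctx$weight_kg)
  expect_equal(back$context$elapsed_s, ctx$elapsed_s)
})

test_that("label maps round-trip through the segmentation DICOM object", {
  tr <- tiny_phantom()
  reg <- default_registry()
  lab <- tr$labels$labels
  lab[lab == 1L] <- 50L; lab[lab == 2L] <- 3L
  lm <- label_map(lab, tr$labels$grid, reg)
  f <- tempfile(fileext = ".dcm")
  set.seed(6)
  write_labelmap_dicom(lm, reg, f)
  back <- read_labelmap_dicom(f, reg)
  expect_identical(back$labels, lm$labels)
  segs <- attr(back, "segment_labels")
  expect_equal(unname(segs[as.character(c(3L, 50L))]),
               reg$name[match(c(3L, 50L), reg$index)])

  # empty label map -> valid all-background file
  emp <- label_map(array(0L, c(4, 4, 2)), image_grid(c(4, 4, 2), c(1, 1, 1)))
  f2 <- tempfile(fileext = ".dcm")
  write_labelmap_dicom(emp, NULL, f2)
  back2 <- read_labelmap_dicom(f2)
  expect_true(all(back2$labels == 0L))
})

test_that("a 100-label map preserves every registry name", {
  reg <- default_registry()
  g <- image_grid(c(10, 10, 1), c(1, 1, 1))
  lab <- label_map(array(c(1:100), c(10, 10, 1)), g, reg)
  f <- tempfile(fileext = ".dcm")
  set.seed(7)
  write_labelmap_dicom(lab, reg, f)
  back <- read_labelmap_dicom(f, reg)
  expect_identical(back$labels, lab$labels)
  segs <- attr(back, "segment_labels")
  expect_equal(unname(segs[as.character(1:100)]), reg$name)
})

test_that("NIfTI volumes and label maps round-trip", {
  tr <- tiny_phantom(noise_sd = 10)
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(tr$ct, f)
  back <- read_volume_nifti(f, "CT_HU")
  expect_equal(back$values, tr$ct$values, tolerance = 1e-12)
  expect_equal(back$grid$spacing, tr$ct$grid$spacing)

  f2 <- tempfile(fileext = ".nii.gz")
  write_labelmap_nifti(tr$labels, f2)
  lback <- read_labelmap_nifti(f2)
  expect_identical(lback$labels, tr$labels$labels)
})

test_that("de-identification removes or replaces every profiled attribute value", {
  tr <- tiny_phantom(noise_sd = 0)
  din <- file.path(tempdir(), "deid_in"); dout <- file.path(tempdir(), "deid_out")
  unlink(c(din, dout), recursive = TRUE)
  set.seed(8)
  patient <- list(name = "DOE^JOHN", id = "PAT123987", birth_date = "19561224",
                  sex = "M")
  write_ct_dicom(tr$ct, din, patient = patient)
  session <- deidentify_files(din, dout)

  # byte-scan: none of the identifying values survive anywhere in any file
  secrets <- c("DOE^JOHN", "PAT123987", "19561224", "ACC123456",
               "General Hospital Alpha", "REFERRER^DOC")
  for (f in list.files(dout, full.names = TRUE)) {
    b <- readBin(f, "raw", n = file.info(f)$size)
    for (s in secrets)
      expect_equal(length(grepRaw(s, b, fixed = TRUE, all = TRUE)), 0L,
                   info = paste(basename(f), s))
  }
  # pixel data untouched
  expect_equal(read_ct_series(dout)$values, tr$ct$values)
})

test_that("UID remapping is consistent within a session and preserves linkage", {
  tr <- tiny_phantom(noise_sd = 0)
  din <- file.path(tempdir(), "deid_in2"); dout <- file.path(tempdir(), "deid_out2")
  unlink(c(din, dout), recursive = TRUE)
  set.seed(9)
  write_ct_dicom(tr$ct, din)
  orig <- lapply(list.files(din, full.names = TRUE), dicom_read)
  deidentify_files(din, dout)
  new <- lapply(list.files(dout, full.names = TRUE), dicom_read)

  o_series <- vapply(orig, function(d) dcm_get(d, "SeriesInstanceUID"), character(1))
  n_series <- vapply(new, function(d) dcm_get(d, "SeriesInstanceUID"), character(1))
  expect_equal(length(unique(n_series)), 1L)         # linkage preserved
  expect_false(unique(n_series) %in% o_series)       # but remapped
  n_sop <- vapply(new, function(d) dcm_get(d, "SOPInstanceUID"), character(1))
  expect_false(any(duplicated(n_sop)))               # injection
})

test_that("de-identification is idempotent on attribute values", {
  tr <- tiny_phantom(noise_sd = 0)
  d0 <- file.path(tempdir(), "deid_a"); d1 <- file.path(tempdir(), "deid_b")
  d2 <- file.path(tempdir(), "deid_c")
  unlink(c(d0, d1, d2), recursive = TRUE)
  set.seed(10)
  write_ct_dicom(tr$ct, d0)
  s <- deidentify_files(d0, d1)
  deidentify_files(d1, d2, session = s)   # same session: full no-op
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_equal(f1, f2)
  for (f in f1) {
    a <- dicom_read(file.path(d1, f)); b <- dicom_read(file.path(d2, f))
    expect_equal(a, b)
  }
})

test_that("dates can be shifted consistently instead of removed", {
  ds <- list(dcm_element("SOPClassUID", "1.2.840.10008.5.1.4.1.1.2"),
             dcm_element("SOPInstanceUID", dcm_new_uid()),
             dcm_element("StudyDate", "20200115"),
             dcm_element("SeriesDate", "20200117"),
             dcm_element("PatientName", "DOE^JANE"))
  prof <- deid_profile(retain_longitudinal = TRUE)
  out <- deidentify_dataset(ds, prof, deid_session(date_shift_days = 10))
  sd <- dcm_get(out, "StudyDate"); se <- dcm_get(out, "SeriesDate")
  expect_equal(sd, "20200105")
  # interval preserved under the shift
  expect_equal(as.integer(as.Date(se, "%Y%m%d") - as.Date(sd, "%Y%m%d")), 2L)
  expect_equal(dcm_get(out, "PatientName"), "ANONYMOUS")
})
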