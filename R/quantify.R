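#' Per-label statistics over a segmentation
#'
#' For every label: volume in ml (voxel count times voxel volume, exact),
#' mean and max of the co-registered value volume, the number of
#' 26-connected components, and the total uptake (sum of voxel values times
#' voxel volume, which equals mean times volume).
#'
#' @param labels a [label_map()].
#' @param values a [volume()] on the same grid (CT, PET activity or SUV).
#' @param registry optional [label_registry] supplying names.
#' @param which_labels labels to report; defaults to those present in the
#'   map (empty requested labels emit a zero-volume row).
#' @param connectivity component connectivity (26 default).
#' @return A data frame of class `quant_report` with columns `label`,
#'   `name`, `volume_ml`, `mean`, `max`, `components`, `total_uptake`, and
#'   a `units` attribute taken from the value volume.
#' @examples
#' g <- image_grid(c(10, 10, 1), c(1, 1, 1))
#' lab <- label_map(array(rep(1L, 100), c(10, 10, 1)), g)
#' pet <- volume(array(5, c(10, 10, 1)), g, "PET_ACTIVITY")
#' label_stats(lab, pet)
#' @export
label_stats <- function(labels, values, registry = NULL, which_labels = NULL,
                        connectivity = 26L) {
  stopifnot(inherits(labels, "label_map"), inherits(values, "volume"))
  if (!identical(labels$grid$shape, values$grid$shape))
    stop("label and value grids do not match")
  vml <- voxel_volume_ml(labels$grid)
  lv <- labels$labels
  if (is.null(which_labels))
    which_labels <- sort(setdiff(unique(as.vector(lv)), 0L))
  rows <- lapply(which_labels, function(k) {
    m <- lv == k
    n <- sum(m)
    if (n == 0L)
      return(data.frame(label = k, volume_ml = 0, mean = NA_real_,
                        max = NA_real_, components = 0L, total_uptake = 0))
    vals <- values$values[m]
    comp <- attr(cpp_cc3d(array(as.integer(m), dim(m)), dim(m),
                          as.integer(connectivity)), "n_components")
    data.frame(label = k, volume_ml = n * vml, mean = mean(vals),
               max = max(vals), components = comp,
               total_uptake = sum(vals) * vml)
  })
  out <- do.call(rbind, rows)
  if (!is.null(registry))
    out <- cbind(out[, "label", drop = FALSE],
                 name = registry$name[match(out$label, registry$index)],
                 out[, setdiff(names(out), "label")])
  attr(out, "units") <- values$units
  class(out) <- c("quant_report", "data.frame")
  out
}

#' Radiopharmaceutical context for SUV computation
#'
#' @param dose_bq injected dose in Bq at injection time (> 0).
#' @param half_life_s radionuclide half-life in seconds (> 0).
#' @param weight_kg patient weight in kg (> 0).
#' @param elapsed_s seconds from injection to scan start (>= 0); ignored
#'   when `decay_corrected` is TRUE.
#' @param decay_corrected TRUE when the stored activity values are already
#'   decay-corrected to injection time.
#' @return A list of class `suv_context`.
#' @export
suv_context <- function(dose_bq, half_life_s, weight_kg, elapsed_s = 0,
                        decay_corrected = FALSE) {
  if (any(!is.finite(c(dose_bq, half_life_s, weight_kg))) ||
      dose_bq <= 0 || half_life_s <= 0 || weight_kg <= 0)
    stop("dose, half-life and weight must be positive")
  if (elapsed_s < 0) stop("elapsed time must be >= 0")
  structure(list(dose_bq = dose_bq, half_life_s = half_life_s,
                 weight_kg = weight_kg, elapsed_s = elapsed_s,
                 decay_corrected = decay_corrected),
            class = "suv_context")
}

#' Multiplicative factor from activity concentration to body-weight SUV
#'
#' SUVbw normalises activity concentration (Bq/ml) by the injected dose per
#' gram of body weight, with the dose decay-corrected to scan start:
#' `factor = weight_g / (dose_bq * 2^(-elapsed / half_life))`. Applying the
#' factor to Bq/ml values yields dimensionless SUV (1 g/ml tissue density
#' convention). One half-life of elapsed time doubles the factor.
#'
#' @param context an [suv_context()].
#' @return Scalar factor per (Bq/ml); multiply kBq/ml values by
#'   `1000 * suv_scale(context)`.
#' @examples
#' # 10 kBq/ml, 100 MBq injected (no decay), 70 kg -> SUV 7.0
#' 10 * 1000 * suv_scale(suv_context(1e8, half_life_s = 6586.2, weight_kg = 70))
#' @export
suv_scale <- function(context) {
  stopifnot(inherits(context, "suv_context"))
  decayed <- if (context$decay_corrected) context$dose_bq
  else context$dose_bq * 2^(-context$elapsed_s / context$half_life_s)
  (context$weight_kg * 1000) / decayed
}

#' Convert a PET activity volume to SUV
#'
#' @param pet a `PET_ACTIVITY` [volume()] (kBq/ml by default; Bq/ml
#'   honoured via the volume's `units` field).
#' @param context an [suv_context()], or `NULL`. A missing context yields
#'   the input unchanged with a warning, so reports are still emitted
#'   without SUV scaling.
#' @return A `PET_SUV` [volume()].
#' @export
suv_volume <- function(pet, context) {
  stopifnot(inherits(pet, "volume"))
  if (pet$modality != "PET_ACTIVITY") stop("suv_volume expects a PET_ACTIVITY volume")
  if (is.null(context)) {
    warning("no radiopharmaceutical context; values left as activity concentration")
    return(pet)
  }
  per_bqml <- suv_scale(context)
  f <- if (identical(pet$units, "Bq/ml")) per_bqml else 1000 * per_bqml
  volume(pet$values * f, pet$grid, "PET_SUV")
}

#' Total uptake per label
#'
#' The integral of the value volume over each label: sum of voxel values
#' times voxel volume. On an SUV volume this is the total lesion uptake;
#' it equals mean x volume for every label.
#'
#' @param labels a [label_map()].
#' @param values a [volume()] on the same grid (typically `PET_SUV`).
#' @param which_labels labels to report; defaults to those present.
#' @return Data frame with `label` and `total_uptake`.
#' @export
total_uptake <- function(labels, values, which_labels = NULL) {
  st <- label_stats(labels, values, which_labels = which_labels)
  st[, c("label", "total_uptake")]
}

#' Export a quantification or metrics report as CSV
#'
#' One row per label with locale-independent numeric formatting; parsing
#' the file back reproduces the numbers to printed precision.
#'
#' @param report a data frame (`quant_report`, `metrics_table`, ...).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(report, path) {
  df <- as.data.frame(report)
  if (!length(names(df))) stop("report must have a non-empty header")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
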