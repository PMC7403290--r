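# Desk-scale study conditions: the seeded phantom populations on which the
# package's training and evaluation experiments run. The defaults ARE the
# experimental conditions; they are not tuning knobs.

#' Desk-scale semantic-segmentation phantom
#'
#' A 64^3 voxel, (2, 2, 3) mm CT phantom with three organs on an air
#' background: a lung-like ellipsoid (-700 HU), a liver-like ellipsoid
#' (60 HU) and a bone-like box (700 HU), each with per-voxel HU jitter,
#' plus 20 HU global noise. Organ positions and sizes vary moderately with
#' the seed, emulating inter-patient variability.
#'
#' @param seed integer seed (also the phantom id).
#' @return A [generate_phantom()] result.
#' @export
desk_semantic_phantom <- function(seed = 1L) {
  reg <- default_registry()
  lab <- function(nm) reg$index[match(nm, reg$name)]
  set.seed(seed + 1000L)
  jit <- function(x, frac = 0.1) x * stats::runif(length(x), 1 - frac, 1 + frac)
  mv <- function(x, mm = 6) x + stats::runif(length(x), -mm, mm)
  grid <- image_grid(c(64, 64, 64), c(2, 2, 3))
  organs <- list(
    list(label = lab("Lung left"), shape = "ellipsoid",
         centre_mm = mv(c(40, 64, 130)), radii_mm = jit(c(22, 26, 34)),
         hu_mean = -700, hu_jitter_sd = 30),
    list(label = lab("Liver"), shape = "ellipsoid",
         centre_mm = mv(c(80, 62, 70)), radii_mm = jit(c(30, 26, 30)),
         hu_mean = 60, hu_jitter_sd = 15),
    list(label = lab("Hip bone left"), shape = "box",
         centre_mm = mv(c(40, 64, 40), 4), radii_mm = jit(c(14, 14, 18)),
         hu_mean = 700, hu_jitter_sd = 40))
  generate_phantom(phantom_spec(grid, organs, background_hu = -1000,
                                noise_sd = 20, seed = seed))
}

#' The semantic-network labels of the desk phantom task
#' @return Integer vector of the three registry labels.
#' @export
desk_semantic_labels <- function() {
  reg <- default_registry()
  reg$index[match(c("Lung left", "Liver", "Hip bone left"), reg$name)]
}

#' Desk-scale spine phantom
#'
#' A 48 x 48 x 64 voxel, (2, 2, 3) mm phantom containing only a spine of
#' vertebra-like instances (700 HU ellipsoids with z-jitter) on an air
#' background, the input for instance-network training and
#' centre-clustering experiments.
#'
#' @param seed integer seed.
#' @param n_vertebrae number of vertebra instances.
#' @param rib_pairs_range rib pairs per vertebra, `c(lo, hi)`.
#' @return A [generate_phantom()] result.
#' @export
desk_spine_phantom <- function(seed = 1L, n_vertebrae = 5L,
                               rib_pairs_range = c(0L, 0L)) {
  grid <- image_grid(c(48, 48, 64), c(2, 2, 3))
  sp <- spine_spec(n_vertebrae = n_vertebrae, size_mm = c(36, 30, 15),
                   gap_mm = 9, rib_pairs_range = rib_pairs_range)
  generate_phantom(phantom_spec(grid, spine = sp, background_hu = -1000,
                                noise_sd = 20, seed = seed))
}

#' Desk-scale training populations
#'
#' Seeded lists of phantoms for the package's learning experiments:
#' `desk_semantic_set()` returns `n` semantic phantoms (seeds
#' `seed_base + 1..n`), `desk_spine_set()` returns `n` spine phantoms with
#' vertebra counts cycling over `n_vertebrae`.
#'
#' @param n number of phantoms.
#' @param seed_base offset added to each phantom's seed.
#' @param n_vertebrae integer vector of vertebra counts to cycle through.
#' @return List of [generate_phantom()] results.
#' @export
desk_semantic_set <- function(n = 20L, seed_base = 0L) {
  lapply(seq_len(n), function(i) desk_semantic_phantom(seed_base + i))
}

#' @rdname desk_semantic_set
#' @export
desk_spine_set <- function(n = 10L, seed_base = 0L, n_vertebrae = 3:8) {
  lapply(seq_len(n), function(i)
    desk_spine_phantom(seed_base + i,
                       n_vertebrae = n_vertebrae[((i - 1L) %% length(n_vertebrae)) + 1L]))
}
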