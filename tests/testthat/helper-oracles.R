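# Independent brute-force oracles used across the suite. These deliberately
# use naive enumeration (or igraph, a package the implementation does not
# use) so they stay independent of the code paths they check.

# Voxel-by-voxel confusion counts by explicit loop.
bf_confusion <- function(pred, truth, labels) {
  out <- data.frame(label = labels, tp = 0L, fp = 0L, fn = 0L)
  pv <- as.vector(pred); tv <- as.vector(truth)
  for (i in seq_along(pv)) {
    for (j in seq_along(labels)) {
      k <- labels[j]
      if (pv[i] == k && tv[i] == k) out$tp[j] <- out$tp[j] + 1L
      else if (pv[i] == k) out$fp[j] <- out$fp[j] + 1L
      else if (tv[i] == k) out$fn[j] <- out$fn[j] + 1L
    }
  }
  out
}

# Connected components via igraph on the voxel adjacency graph.
bf_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  vox <- which(mask != 0)
  if (!length(vox)) return(list(n = 0L, membership = integer(0), vox = vox))
  co <- arrayInd(vox, d)
  id <- seq_along(vox)
  edges <- list()
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  key <- co[, 1] + (co[, 2] - 1) * d[1] + (co[, 3] - 1) * d[1] * d[2]
  lut <- integer(prod(d)); lut[key] <- id
  for (r in seq_len(nrow(offs))) {
    nb <- cbind(co[, 1] + offs$dx[r], co[, 2] + offs$dy[r], co[, 3] + offs$dz[r])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nk <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
    hit <- lut[nk] > 0
    if (any(hit))
      edges[[length(edges) + 1]] <- cbind(id[ok][hit], lut[nk][hit])
  }
  g <- igraph::graph_from_edgelist(unique(do.call(rbind, c(list(cbind(id, id)), edges))),
                                   directed = FALSE)
  comp <- igraph::components(g)
  list(n = comp$no, membership = comp$membership[seq_along(vox)], vox = vox)
}

# Hole filling oracle: flood the background from the border (6-connectivity)
# with an explicit queue; anything background and unreached is a hole.
bf_fill_holes <- function(mask) {
  d <- dim(mask)
  reach <- array(FALSE, d)
  q <- which(!mask &
               (slice.index(mask, 1) %in% c(1, d[1]) |
                  slice.index(mask, 2) %in% c(1, d[2]) |
                  slice.index(mask, 3) %in% c(1, d[3])))
  reach[q] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (length(q)) {
    cur <- q[length(q)]; q <- q[-length(q)]
    co <- arrayInd(cur, d)
    for (r in 1:6) {
      nb <- co + offs[r, ]
      if (any(nb < 1) || any(nb > d)) next
      ni <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
      if (!mask[ni] && !reach[ni]) { reach[ni] <- TRUE; q <- c(q, ni) }
    }
  }
  mask | (!mask & !reach)
}

# Random small binary mask with tunable density.
random_mask <- function(seed, dim = c(12, 12, 8), p = 0.25) {
  set.seed(seed)
  array(stats::runif(prod(dim)) < p, dim)
}

tiny_grid <- function(shape = c(8, 8, 8), spacing = c(1, 1, 1))
  image_grid(shape, spacing)

# A minimal noiseless two-organ phantom for I/O and metric tests.
tiny_phantom <- function(seed = 1, noise_sd = 0) {
  grid <- image_grid(c(16, 16, 12), c(2, 2, 3))
  organs <- list(
    list(label = 1L, shape = "ellipsoid", centre_mm = c(10, 14, 12),
         radii_mm = c(7, 7, 8), hu_mean = 60),
    list(label = 2L, shape = "box", centre_mm = c(22, 18, 22),
         radii_mm = c(5, 5, 6), hu_mean = 700))
  generate_phantom(phantom_spec(grid, organs, background_hu = -1000,
                                noise_sd = noise_sd, seed = seed))
}
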