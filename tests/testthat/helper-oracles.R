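# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force (vectorized R), never
# through the package's own kernels.

# Exhaustive capsule-distance rasterization: voxel is foreground iff its
# center lies within the interpolated radius of the sampled polyline.
oracle_tube_mask <- function(pts, radii, dims) {
  stopifnot(nrow(pts) == length(radii))
  g <- as.matrix(expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                             z = seq_len(dims[3L])))
  fg <- rep(FALSE, nrow(g))
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    u <- b - a
    len2 <- sum(u^2)
    v <- sweep(g, 2L, a)
    t <- if (len2 > 0) pmin(pmax((v %*% u) / len2, 0), 1) else rep(0, nrow(g))
    d2 <- rowSums((v - t %*% t(u))^2)
    r <- radii[s] + t * (radii[s + 1L] - radii[s])
    fg <- fg | (d2 <= r^2)
  }
  array(fg, dims)
}

# Per-row distance of points to the nearest dense ground-truth curve sample.
dist_to_truth <- function(pts, truth) {
  tp <- t(as.matrix(truth[, c("x", "y", "z")]))
  apply(pts, 1L, function(p) sqrt(min(colSums((tp - p)^2))))
}

rmse_to_truth <- function(pts, truth) sqrt(mean(dist_to_truth(pts, truth)^2))

# Brute-force cubic-neighborhood median with edge replication.
oracle_median3d <- function(a, k) {
  d <- dim(a)
  r <- k %/% 2
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  out <- array(0, d)
  for (z in seq_len(d[3L])) for (y in seq_len(d[2L])) for (x in seq_len(d[1L]))
    out[x, y, z] <- stats::median(a[cl((x - r):(x + r), d[1L]),
                                    cl((y - r):(y + r), d[2L]),
                                    cl((z - r):(z + r), d[3L])])
  out
}

# Brute-force ball morphology on small grids: erosion keeps voxels whose
# entire ball neighborhood (clipped at the grid edge counts as background)
# is foreground; dilation marks every ball neighbor of a foreground voxel.
oracle_ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, ])
}

oracle_open <- function(fg, radius) {
  d <- dim(fg)
  offs <- oracle_ball_offsets(radius)
  idx <- which(fg, arr.ind = TRUE)
  er <- array(FALSE, d)
  for (i in seq_len(nrow(idx))) {
    p <- sweep(offs, 2L, idx[i, ], "+")
    inside <- p[, 1L] >= 1 & p[, 1L] <= d[1L] & p[, 2L] >= 1 &
      p[, 2L] <= d[2L] & p[, 3L] >= 1 & p[, 3L] <= d[3L]
    if (all(inside) && all(fg[p])) er[idx[i, 1L], idx[i, 2L], idx[i, 3L]] <- TRUE
  }
  di <- array(FALSE, d)
  idx <- which(er, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    p <- sweep(offs, 2L, idx[i, ], "+")
    keep <- p[, 1L] >= 1 & p[, 1L] <= d[1L] & p[, 2L] >= 1 &
      p[, 2L] <= d[2L] & p[, 3L] >= 1 & p[, 3L] <= d[3L]
    di[p[keep, , drop = FALSE]] <- TRUE
  }
  di
}

# Cylinder-with-debris fixture shared by the morphology tests.
debris_cylinder <- function() {
  d <- c(80L, 64L, 64L)
  xi <- seq_len(d[1L]); yi <- seq_len(d[2L]); zi <- seq_len(d[3L])
  cyl <- array(outer((xi - 40)^2, (yi - 32)^2, "+") <= 625, d)
  dist2 <- outer(outer((xi - 70)^2, (yi - 32)^2, "+"), (zi - 32)^2, "+")
  blob <- dist2 <= 100
  list(mask = lumen_mask(array(as.integer(cyl | blob), d)),
       cyl = cyl, blob = blob, dims = d)
}

# Four-slab class map used by the histogram tests.
slab_class_map <- function(dims = c(64L, 64L, 256L)) {
  array(rep(1:4, each = prod(dims) / 4L), dims)
}
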