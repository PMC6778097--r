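#' 3D median smoothing
#'
#' Replaces every voxel by the median of its `kernel^3` cubic neighborhood,
#' the standard despeckling step before region growing. Borders are handled
#' by edge replication so foreground touching the volume faces is not
#' shrunk. The default kernel edge of 15 voxels matches the preprocessing
#' used for artery tomograms; on a soft-edged lumen it moves the
#' half-maximum boundary outward by about one voxel.
#'
#' @param v a [voxel_volume()].
#' @param kernel odd neighborhood edge length in voxels.
#' @return a smoothed [voxel_volume()].
#' @export
median_smooth <- function(v, kernel = 15L) {
  stopifnot(inherits(v, "voxel_volume"))
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("'kernel' must be an odd integer >= 1")
  out <- cpp_median3d(as.numeric(v$data), dim(v$data), kernel)
  voxel_volume(array(out, dim(v$data)), v$voxel_length, v$name)
}

#' Seeded region growing
#'
#' Grows the 26-connected region reachable from the seed voxels through
#' voxels whose intensity lies within `tolerance` of the mean seed
#' intensity. This reimplements the interactive region-growing segmentation
#' step as a fixed-tolerance criterion; the tolerance is the exposed knob.
#'
#' @param v a [voxel_volume()].
#' @param seeds integer matrix (or length-3 vector) of 1-based voxel
#'   coordinates, one seed per row.
#' @param tolerance intensity half-width around the seed mean.
#' @return a [lumen_mask()].
#' @export
region_grow <- function(v, seeds, tolerance) {
  stopifnot(inherits(v, "voxel_volume"), tolerance >= 0)
  if (is.vector(seeds)) seeds <- matrix(seeds, nrow = 1L)
  seeds <- apply(seeds, 2L, as.integer)
  if (is.vector(seeds)) seeds <- matrix(seeds, nrow = 1L)
  if (ncol(seeds) != 3L || nrow(seeds) < 1L)
    stop("'seeds' must be an n x 3 matrix of voxel coordinates")
  d <- dim(v$data)
  if (any(seeds < 1L) || any(seeds[, 1L] > d[1L]) ||
      any(seeds[, 2L] > d[2L]) || any(seeds[, 3L] > d[3L]))
    stop("seed outside the volume grid")
  ref <- mean(v$data[seeds])
  grown <- cpp_region_grow(as.numeric(v$data), d, seeds, ref, tolerance)
  lumen_mask(array(as.integer(grown), d), v$voxel_length, v$name)
}

#' Morphological opening with a Euclidean ball
#'
#' Erosion by a discrete ball of the given radius followed by dilation with
#' the same ball. Removes attached structures (debris) thinner than the
#' ball while retaining the main lumen; a radius of 0 is the identity. The
#' opening never adds voxels: its output is a subset of the input
#' foreground. Implemented exactly via squared Euclidean distance
#' transforms.
#'
#' @param m a [lumen_mask()].
#' @param radius ball radius in voxels (the cleanup used for
#'   debris-contaminated data is radius 20).
#' @return an opened [lumen_mask()].
#' @export
morph_open <- function(m, radius) {
  stopifnot(inherits(m, "lumen_mask"), radius >= 0)
  if (radius == 0) return(m)
  d <- dim(m$data)
  eroded <- erode_ball(m$data > 0, d, radius)
  opened <- dilate_ball(eroded, d, radius)
  lumen_mask(array(as.integer(opened), d), m$voxel_length, m$name)
}

# erosion: keep foreground voxels whose distance to the nearest background
# voxel exceeds the ball radius (so the full ball fits inside)
erode_ball <- function(fg, d, radius) {
  dist_bg <- cpp_edt_sq(!fg, d)
  array(fg & dist_bg > radius^2, d)
}

dilate_ball <- function(fg, d, radius) {
  if (!any(fg)) return(array(FALSE, d))
  dist_fg <- cpp_edt_sq(fg, d)
  array(dist_fg <= radius^2, d)
}

#' Segmentation parameter bundle
#'
#' Collects the preprocessing parameters: median kernel edge (default 15),
#' region-growing tolerance and seeds, and opening radius (default 0; 20 is
#' used for debris-contaminated data).
#'
#' @param median_kernel odd median neighborhood edge, voxels.
#' @param grow_tolerance intensity half-width for region growing.
#' @param seeds `n x 3` matrix of seed voxel coordinates.
#' @param opening_radius ball radius for the final opening, voxels.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(median_kernel = 15L, grow_tolerance = 0.5,
                                seeds = NULL, opening_radius = 0L) {
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 1L || median_kernel %% 2L == 0L)
    stop("'median_kernel' must be odd and >= 1")
  if (opening_radius < 0) stop("'opening_radius' must be >= 0")
  structure(list(median_kernel = median_kernel,
                 grow_tolerance = grow_tolerance, seeds = seeds,
                 opening_radius = as.integer(opening_radius)),
            class = "segmentation_params")
}

#' Run the full segmentation chain
#'
#' Median smoothing, seeded region growing, then ball opening, in that
#' order.
#'
#' @param v a grayscale [voxel_volume()].
#' @param params a [segmentation_params()]; must carry at least one seed.
#' @return a [lumen_mask()].
#' @export
segment_lumen <- function(v, params) {
  stopifnot(inherits(params, "segmentation_params"))
  if (is.null(params$seeds))
    stop("region growing requires at least one seed")
  sm <- median_smooth(v, params$median_kernel)
  m <- region_grow(sm, params$seeds, params$grow_tolerance)
  morph_open(m, params$opening_radius)
}
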