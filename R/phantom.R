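#' Specify a synthetic tube phantom
#'
#' A tube is defined by a parametric center curve `p(t)`, `t` in `[0, 1]`, and
#' a radius profile `r(t)` in voxel units. The curve may be an analytic
#' function returning an `n x 3` matrix of 1-based voxel coordinates, or a
#' matrix of control points that is interpolated linearly. A blind-ended
#' cylindrical appendage (see [branch_spec()]) emulates a bifurcation stub.
#'
#' Sub-voxel tubes are not representable: `r(t) >= 2` is required everywhere.
#' The tube must stay inside the grid in x and y with its full radius; it may
#' meet the z faces (a vessel crossing the imaged volume ends at the stack
#' faces).
#'
#' @param curve function of `t` (vectorized, returns `n x 3` matrix) or an
#'   `m x 3` matrix of control points interpolated linearly in `t`.
#' @param radius function of `t` returning radii in voxels, or a single
#'   number for a constant radius.
#' @param grid_shape integer vector of 3 positive grid dimensions.
#' @param branch optional [branch_spec()].
#' @return an object of class `tube_spec`.
#' @export
tube_spec <- function(curve, radius, grid_shape, branch = NULL) {
  if (is.matrix(curve)) {
    cp <- curve
    stopifnot(ncol(cp) == 3L, nrow(cp) >= 2L)
    curve <- function(t) {
      s <- t * (nrow(cp) - 1L) + 1
      i0 <- pmin(pmax(floor(s), 1L), nrow(cp) - 1L)
      f <- s - i0
      cp[i0, , drop = FALSE] * (1 - f) + cp[i0 + 1L, , drop = FALSE] * f
    }
  }
  stopifnot(is.function(curve))
  if (is.numeric(radius) && length(radius) == 1L) {
    r0 <- radius
    radius <- function(t) rep(r0, length(t))
  }
  stopifnot(is.function(radius))
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  spec <- structure(list(curve = curve, radius = radius,
                         grid_shape = grid_shape, branch = branch),
                    class = "tube_spec")
  validate_tube_spec(spec)
  spec
}

#' Specify a bifurcation appendage
#'
#' A blind-ended cylinder attached to the parent tube at curve parameter
#' `attach_t`, reproducing the bulge-inducing geometry of a vessel
#' bifurcation without modelling a full second vessel.
#'
#' @param attach_t attachment parameter on the parent curve, in (0, 1).
#' @param direction 3D direction of the appendage axis (normalized
#'   internally).
#' @param length appendage length in voxels.
#' @param radius appendage radius in voxels; must not exceed the parent
#'   radius at `attach_t`.
#' @return an object of class `branch_spec`.
#' @export
branch_spec <- function(attach_t, direction, length, radius) {
  stopifnot(attach_t > 0, attach_t < 1, length > 0, radius >= 2)
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3L, sum(direction^2) > 0)
  structure(list(attach_t = attach_t,
                 direction = direction / sqrt(sum(direction^2)),
                 length = length, radius = radius),
            class = "branch_spec")
}

validate_tube_spec <- function(spec, n = 201L) {
  t <- seq(0, 1, length.out = n)
  p <- spec$curve(t)
  r <- spec$radius(t)
  if (any(r < 2))
    stop("radius profile must be >= 2 voxels everywhere")
  g <- spec$grid_shape
  if (any(p[, 1L] - r < 0.5) || any(p[, 1L] + r > g[1L] + 0.5) ||
      any(p[, 2L] - r < 0.5) || any(p[, 2L] + r > g[2L] + 0.5))
    stop("tube exits the grid in x/y; enlarge the grid or shrink the tube")
  if (any(p[, 3L] < 0.5) || any(p[, 3L] > g[3L] + 0.5))
    stop("curve exits the grid in z")
  if (!is.null(spec$branch)) {
    b <- spec$branch
    rt <- spec$radius(b$attach_t)
    if (b$radius > rt)
      stop("branch radius exceeds parent radius at the attachment point")
    p0 <- drop(spec$curve(b$attach_t))
    ends <- rbind(p0, p0 + b$direction * (rt + b$length))
    if (any(ends[, 1L] - b$radius < 0.5) ||
        any(ends[, 1L] + b$radius > g[1L] + 0.5) ||
        any(ends[, 2L] - b$radius < 0.5) ||
        any(ends[, 2L] + b$radius > g[2L] + 0.5) ||
        any(ends[, 3L] - b$radius < 0.5) ||
        any(ends[, 3L] + b$radius > g[3L] + 0.5))
      stop("branch exits the grid")
  }
  invisible(spec)
}

#' Rasterize a tube phantom with analytic ground truth
#'
#' A voxel is foreground iff its center lies within the local radius of the
#' center curve (distance to the densely sampled polyline, with the radius
#' interpolated along it — a union of capsules); branch voxels are unioned
#' in when a [branch_spec()] is present. No antialiasing is applied, so an
#' exhaustive center-in-capsule test reproduces the generator exactly.
#'
#' @param spec a [tube_spec()].
#' @param n_samples number of dense curve samples used for rasterization and
#'   ground truth (default targets ~4 samples per voxel of curve length).
#' @param voxel_length physical voxel length in micrometers attached to the
#'   output mask.
#' @return a list with elements `mask` (a [lumen_mask()]) and `truth`, a
#'   data frame with columns `t, x, y, z, r, area, arclength` (`area` is the
#'   analytic orthogonal section `pi * r(t)^2` in voxel^2, `arclength` the
#'   cumulative curve length in voxels).
#' @export
make_tube <- function(spec, n_samples = NULL, voxel_length = 1) {
  stopifnot(inherits(spec, "tube_spec"))
  t0 <- seq(0, 1, length.out = 257L)
  p0 <- spec$curve(t0)
  len <- sum(sqrt(rowSums(diff(p0)^2)))
  if (is.null(n_samples)) n_samples <- max(257L, ceiling(len * 4))
  t <- seq(0, 1, length.out = n_samples)
  p <- spec$curve(t)
  r <- spec$radius(t)
  arr <- cpp_rasterize_tube(p, r, spec$grid_shape)
  if (!is.null(spec$branch)) {
    b <- spec$branch
    p0b <- drop(spec$curve(b$attach_t))
    bp <- rbind(p0b, p0b + b$direction * (spec$radius(b$attach_t) + b$length))
    arr <- arr | cpp_rasterize_tube(bp, rep(b$radius, 2L), spec$grid_shape)
  }
  mask <- lumen_mask(array(as.integer(arr), spec$grid_shape), voxel_length)
  arcl <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  # The tube is a union of spheres (a canal surface): where the radius
  # profile has a steep arclength gradient, the exact orthogonal section is
  # the envelope max_j (r_j^2 - (s_j - s_i)^2), slightly larger than the
  # nominal circle pi r^2. Both are reported.
  rmax <- max(r)
  sect <- vapply(seq_along(t), function(i) {
    j <- which(abs(arcl - arcl[i]) <= rmax)
    max(r[j]^2 - (arcl[j] - arcl[i])^2)
  }, numeric(1))
  truth <- data.frame(t = t, x = p[, 1L], y = p[, 2L], z = p[, 3L],
                      r = r, area = pi * r^2, area_section = pi * sect,
                      arclength = arcl)
  list(mask = mask, truth = truth)
}

#' Straight cylinder tilted from the z-axis
#'
#' A straight tube whose axis is tilted by `angle_deg` from the z-axis within
#' the x-z plane. Its ground-truth orthogonal cross-section is
#' `pi * radius^2` independent of the angle, whereas per-z-slice voxel counts
#' grow like `1 / cos(angle)` — the stress case this package's orthogonal
#' profiling is designed for.
#'
#' @param angle_deg tilt angle in degrees, `0 <= angle_deg < 60`.
#' @param radius tube radius in voxels.
#' @param grid_shape integer vector of 3 grid dimensions.
#' @param voxel_length micrometers per voxel.
#' @return as [make_tube()].
#' @export
make_oblique_cylinder <- function(angle_deg, radius, grid_shape,
                                  voxel_length = 1) {
  stopifnot(angle_deg >= 0, angle_deg < 60, radius >= 2)
  grid_shape <- as.integer(grid_shape)
  th <- angle_deg * pi / 180
  nz <- grid_shape[3L]
  cx <- (grid_shape[1L] + 1) / 2
  cy <- (grid_shape[2L] + 1) / 2
  dirv <- c(sin(th), 0, cos(th))
  # the axis overshoots the z faces so that every z plane inside the grid
  # cuts a complete ellipse (the tube is clipped at the faces, with no
  # free end caps inside the volume)
  zc <- (1 + nz) / 2
  half_z <- (nz - 1) / 2 + radius * sin(th) + 1
  half_s <- half_z / cos(th)
  a <- c(cx, cy, zc) - dirv * half_s
  b <- c(cx, cy, zc) + dirv * half_s
  if (min(a[1L], b[1L]) - radius < 0.5 ||
      max(a[1L], b[1L]) + radius > grid_shape[1L] + 0.5 ||
      cy - radius < 0.5 || cy + radius > grid_shape[2L] + 0.5)
    stop("tube exits the grid in x/y; enlarge the grid")
  arr <- cpp_rasterize_tube(rbind(a, b), rep(radius, 2L), grid_shape)
  mask <- lumen_mask(array(as.integer(arr), grid_shape), voxel_length)
  # ground truth restricted to the axis stations inside the volume
  s_in <- seq(-(zc - 1) / cos(th), (nz - zc) / cos(th), length.out = 257L)
  p <- cbind(cx + s_in * dirv[1L], cy, zc + s_in * dirv[3L])
  arcl <- s_in - s_in[1L]
  truth <- data.frame(t = seq(0, 1, length.out = length(s_in)),
                      x = p[, 1L], y = p[, 2L], z = p[, 3L],
                      r = radius, area = pi * radius^2,
                      area_section = pi * radius^2, arclength = arcl)
  list(mask = mask, truth = truth)
}

#' Paired two-modality tissue phantom
#'
#' Given a 3D label map with four tissue classes (emulating embedding
#' paraffin, fibrous tissue, vessel wall and residual plaque), draws each
#' voxel's intensity from the Gaussian of its class, once per modality. With
#' `noise_correlation = 0` the two modalities' noise fields are independent;
#' with 1 they share the same per-voxel noise so identical class parameters
#' yield a diagonal joint histogram.
#'
#' @param class_map 3D integer array with labels `1..4`; all four labels
#'   must be present.
#' @param meansA,sigmasA,meansB,sigmasB length-4 class means and standard
#'   deviations for modalities A and B (all sigmas > 0).
#' @param seed integer seed; the same seed reproduces the volumes exactly.
#' @param noise_correlation per-voxel correlation of the two modalities'
#'   noise, in `[0, 1]`.
#' @param voxel_length micrometers per voxel.
#' @return list of two [voxel_volume()]s, `A` and `B`.
#' @export
make_two_modality_phantom <- function(class_map, meansA, sigmasA,
                                      meansB, sigmasB, seed,
                                      noise_correlation = 0,
                                      voxel_length = 1) {
  class_map <- as.array(class_map)
  stopifnot(length(dim(class_map)) == 3L,
            length(meansA) == 4L, length(sigmasA) == 4L,
            length(meansB) == 4L, length(sigmasB) == 4L,
            all(sigmasA > 0), all(sigmasB > 0),
            noise_correlation >= 0, noise_correlation <= 1)
  labs <- as.integer(class_map)
  if (!all(1:4 %in% labs))
    stop("all four class labels 1..4 must be present in 'class_map'")
  n <- length(labs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eA <- stats::rnorm(n)
  eB0 <- stats::rnorm(n)
  rho <- noise_correlation
  eB <- rho * eA + sqrt(1 - rho^2) * eB0
  a <- array(meansA[labs] + sigmasA[labs] * eA, dim(class_map))
  b <- array(meansB[labs] + sigmasB[labs] * eB, dim(class_map))
  list(A = voxel_volume(a, voxel_length, "modality A"),
       B = voxel_volume(b, voxel_length, "modality B"))
}

#' Built-in phantom presets
#'
#' Named phantoms used throughout the test suite and the reproduction
#' script:
#' \describe{
#'   \item{`straight`}{axis-aligned cylinder, r = 10, length 80.}
#'   \item{`bent`}{circular arc with a 20 degree overall bend, r = 8, length
#'     ~200 voxels.}
#'   \item{`swelling-benchmark`}{the default benchmark: length ~200 voxels,
#'     base radius 8, two Gaussian swellings to r = 14, one constriction to
#'     r = 5, 20 degree bend.}
#'   \item{`bifurcation`}{the bent r = 8 tube plus a thin blind-ended
#'     appendage (r = 2, length 90) leaving the tube midpoint at 45
#'     degrees.}
#' }
#'
#' @param preset preset name.
#' @param voxel_length micrometers per voxel for the generated mask.
#' @return as [make_tube()].
#' @export
phantom_preset <- function(preset = c("straight", "bent",
                                      "swelling-benchmark", "bifurcation"),
                           voxel_length = 1) {
  preset <- match.arg(preset)
  if (preset == "straight") {
    spec <- tube_spec(rbind(c(22, 22, 1), c(22, 22, 80)), 10, c(44, 44, 80))
    return(make_tube(spec, voxel_length = voxel_length))
  }
  # arc spans the full z extent so the tube is clipped at the stack faces
  # (no free end caps), as for a vessel crossing the imaged volume
  bent_curve <- bend_arc_curve(length_vox = 200, angle_deg = 20,
                               center_xy = c(18, 24), z0 = 1)
  grid <- c(72L, 48L, 197L)
  if (preset == "bent") {
    spec <- tube_spec(bent_curve, 8, grid)
    return(make_tube(spec, voxel_length = voxel_length))
  }
  if (preset == "swelling-benchmark") {
    radius <- function(t) {
      8 +
        6 * exp(-0.5 * ((t - 0.25) / 0.05)^2) -
        3 * exp(-0.5 * ((t - 0.50) / 0.04)^2) +
        6 * exp(-0.5 * ((t - 0.75) / 0.05)^2)
    }
    spec <- tube_spec(bent_curve, radius, grid)
    return(make_tube(spec, voxel_length = voxel_length))
  }
  # bifurcation: bent parent plus a thin, long daughter branch (radius a
  # quarter of the parent, as for a small side branch) leaving at 45 degrees
  br <- branch_spec(attach_t = 0.5, direction = c(1, 0, 1) / sqrt(2),
                    length = 90, radius = 2)
  spec <- tube_spec(bent_curve, 8, c(112L, 48L, 197L), branch = br)
  make_tube(spec, voxel_length = voxel_length)
}

# Circular arc in the x-z plane with given total curve length (voxels) and
# overall direction change (degrees), starting upward in z.
bend_arc_curve <- function(length_vox, angle_deg, center_xy, z0) {
  th <- angle_deg * pi / 180
  R <- length_vox / th
  function(t) {
    phi <- t * th
    # arc starts at (0, 0) heading along +z, bending toward +x
    x <- center_xy[1L] + R * (1 - cos(phi))
    y <- rep(center_xy[2L], length(t))
    z <- z0 + R * sin(phi)
    cbind(x, y, z)
  }
}

#' Paired tube phantoms with prescribed segmental shrinkage
#'
#' Emulates the same vessel imaged before and after a preparation step that
#' shrinks the lumen non-uniformly: the baseline is a straight tube (radius
#' 10 voxels, two gentle swellings that serve as alignment landmarks), and
#' the follow-up tube's radius is scaled by `sqrt(scaling)` on three
#' consecutive segments, so cross-sectional areas scale by `scalings`
#' (default area ratios 0.85, 0.65, 0.35, i.e. 15/35/65 percent shrinkage,
#' spanning the range reported for paraffin embedding). The follow-up
#' volume is additionally cropped by `offset_mm`, so its stations start
#' that far into the baseline's coordinate system — the alignment the
#' analysis must recover.
#'
#' @param scalings area ratios of the three segments (after / before).
#' @param offset_mm construction offset of the follow-up volume, mm.
#' @param voxel_length micrometers per voxel (default 10).
#' @return list with `before`, `after` (each as [make_tube()]), `segments`
#'   (before-frame z ranges of the three constant-scaling segments, voxels),
#'   `scalings` and `offset_mm`.
#' @export
make_shrinkage_pair <- function(scalings = c(0.85, 0.65, 0.35),
                                offset_mm = 0.5, voxel_length = 10) {
  stopifnot(length(scalings) == 3L, all(scalings > 0), all(scalings <= 1))
  nz <- 300L
  off_vox <- round(offset_mm * 1000 / voxel_length)
  stopifnot(off_vox < nz - 50L)
  # a dominant plaque-like constriction inside the first segment is the
  # alignment landmark (the real pipeline aligned the two states on the
  # plaque), plus a minor swelling in the last segment; both lie inside
  # the cropped overlap and both shrink with their segment, preserving
  # their shape up to the segmental area ratio
  r0 <- function(z) {
    10 - 4 * exp(-0.5 * ((z - 80) / 8)^2) + 1.5 * exp(-0.5 * ((z - 255) / 6)^2)
  }
  segments <- rbind(c(1, 130), c(140, 215), c(225, nz))
  sc <- function(z) {  # piecewise-constant with 10-voxel linear ramps
    s <- numeric(length(z))
    s[z <= 130] <- scalings[1L]
    ramp1 <- z > 130 & z < 140
    s[ramp1] <- scalings[1L] + (scalings[2L] - scalings[1L]) * (z[ramp1] - 130) / 10
    s[z >= 140 & z <= 215] <- scalings[2L]
    ramp2 <- z > 215 & z < 225
    s[ramp2] <- scalings[2L] + (scalings[3L] - scalings[2L]) * (z[ramp2] - 215) / 10
    s[z >= 225] <- scalings[3L]
    s
  }
  grid_b <- c(48L, 48L, nz)
  before <- make_tube(tube_spec(
    curve = function(t) cbind(24, 24, 1 + t * (nz - 1)),
    radius = function(t) r0(1 + t * (nz - 1)),
    grid_shape = grid_b), voxel_length = voxel_length)
  nz_a <- nz - off_vox
  after <- make_tube(tube_spec(
    curve = function(t) cbind(24, 24, 1 + t * (nz_a - 1)),
    radius = function(t) {
      zb <- off_vox + 1 + t * (nz_a - 1)   # position in the baseline frame
      r0(zb) * sqrt(sc(zb))
    },
    grid_shape = c(48L, 48L, nz_a)), voxel_length = voxel_length)
  # quantification windows: flat stretches away from the landmark
  # swellings and the inter-segment ramps (baseline z, voxels)
  eval_windows <- rbind(c(108, 126), c(145, 210), c(278, 295))
  list(before = before, after = after, segments = segments,
       eval_windows = eval_windows, scalings = scalings,
       offset_mm = off_vox * voxel_length / 1000)
}

#' Write phantom ground truth as a delimited table
#'
#' @param truth the `truth` data frame from [make_tube()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
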