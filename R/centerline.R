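## Iterative relaxation-stabilized centerline estimation.
##
## The centerline of a segmented lumen is initialized from per-slice
## centroids along z, then refined by repeatedly (i) computing tangents by
## second-order finite differences, (ii) resampling the mask on planes
## orthogonal to the tangents, (iii) recentering each point on the centroid
## of the lumen component in its orthogonal plane, (iv) blending with the
## previous iterate through a relaxation parameter beta and smoothing along
## the curve with a Gaussian. Iteration stops when the mean point-wise
## displacement (the residual rho) falls below mu voxel lengths.

#' Gaussian smoothing of a coordinate sequence
#'
#' Smooths a sequence with a discrete Gaussian kernel of standard deviation
#' `sigma` samples. The boundary is extended by antisymmetric (point)
#' reflection about the end values, which preserves constant and linear
#' sequences exactly — so a perfectly straight centerline is a fixed point
#' of the smoothing. `sigma = 0` is the identity. The kernel radius is
#' `min(ceil(3 sigma), n - 1)`.
#'
#' @param x numeric vector.
#' @param sigma Gaussian width in samples.
#' @return smoothed numeric vector of the same length.
#' @export
gauss_smooth1d <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0 || n < 3L) return(x)
  r <- min(ceiling(3 * sigma), n - 1L)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  # antisymmetric reflection: x[1 - j] = 2 x[1] - x[1 + j]
  pre <- 2 * x[1L] - x[seq(r + 1L, 2L, by = -1L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - r, by = -1L)]
  xp <- c(pre, x, post)
  stats::convolve(xp, rev(k), type = "filter")
}

smooth_points <- function(p, sigma) {
  apply(p, 2L, gauss_smooth1d, sigma = sigma)
}

#' Initial centerline from per-slice centroids
#'
#' For every z-slice with foreground, the initial point is the centroid of
#' the foreground voxels in that slice; empty slices at the ends are
#' trimmed and interior empty slices filled by linear interpolation between
#' their neighbors. The three coordinate sequences are then Gaussian
#' smoothed over the slice index. If the lumen is parallel to the z-axis,
#' this initial curve already is the centerline and the subsequent
#' iteration terminates at its first residual check.
#'
#' @param m a [lumen_mask()].
#' @param sigma Gaussian smoothing width in samples along the slice index
#'   (default 20).
#' @return an `n x 3` matrix of continuous points in voxel units.
#' @export
initial_centerline <- function(m, sigma = 20) {
  stopifnot(inherits(m, "lumen_mask"))
  d <- dim(m$data)
  counts <- apply(m$data, 3L, sum)
  nonempty <- which(counts > 0L)
  if (length(nonempty) < 3L)
    stop("mask must have foreground in at least 3 z-slices")
  zr <- seq(min(nonempty), max(nonempty))
  xs <- ys <- rep(NA_real_, length(zr))
  xi <- seq_len(d[1L]); yi <- seq_len(d[2L])
  for (j in seq_along(zr)) {
    z <- zr[j]
    if (counts[z] == 0L) next
    sl <- m$data[, , z]
    xs[j] <- sum(rowSums(sl) * xi) / counts[z]
    ys[j] <- sum(colSums(sl) * yi) / counts[z]
  }
  if (anyNA(xs)) {  # interior gaps: linear interpolation over z
    ok <- !is.na(xs)
    xs <- stats::approx(zr[ok], xs[ok], zr)$y
    ys <- stats::approx(zr[ok], ys[ok], zr)$y
  }
  p <- cbind(x = xs, y = ys, z = as.numeric(zr))
  smooth_points(p, sigma)
}

#' Tangent field of a discrete centerline
#'
#' Unit tangents by second-order finite differences: central differences at
#' interior points, one-sided three-point stencils
#' `(-3 f1 + 4 f2 - f3) / 2` at the endpoints. A zero-length difference is
#' resolved by copying the nearest valid tangent.
#'
#' @param p an `n x 3` matrix of centerline points (n >= 3).
#' @return an `n x 3` matrix of unit tangent vectors.
#' @export
centerline_tangents <- function(p) {
  n <- nrow(p)
  if (n < 3L) stop("need at least 3 centerline points for tangents")
  tau <- matrix(0, n, 3L)
  tau[1L, ] <- (-3 * p[1L, ] + 4 * p[2L, ] - p[3L, ]) / 2
  tau[n, ] <- (3 * p[n, ] - 4 * p[n - 1L, ] + p[n - 2L, ]) / 2
  tau[2:(n - 1L), ] <- (p[3:n, , drop = FALSE] -
                          p[1:(n - 2L), , drop = FALSE]) / 2
  nrm <- sqrt(rowSums(tau^2))
  bad <- which(nrm < 1e-12)
  for (i in bad) {
    good <- which(nrm >= 1e-12)
    tau[i, ] <- tau[good[which.min(abs(good - i))], ]
    nrm[i] <- sqrt(sum(tau[i, ]^2))
  }
  tau / nrm
}

# Deterministic orthonormal in-plane axes for a unit normal.
plane_axes <- function(tangent) {
  ref <- if (abs(tangent[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(tangent[2L] * ref[3L] - tangent[3L] * ref[2L],
         tangent[3L] * ref[1L] - tangent[1L] * ref[3L],
         tangent[1L] * ref[2L] - tangent[2L] * ref[1L])
  u <- u / sqrt(sum(u^2))
  v <- c(tangent[2L] * u[3L] - tangent[3L] * u[2L],
         tangent[3L] * u[1L] - tangent[1L] * u[3L],
         tangent[1L] * u[2L] - tangent[2L] * u[1L])
  list(u = u, v = v)
}

#' Resample a volume on a plane orthogonal to a tangent
#'
#' Extracts a regular 2D grid on the plane through `point` with normal
#' `tangent` by trilinear interpolation of the volume; positions outside
#' the grid sample as 0. The in-plane axes are a deterministic orthonormal
#' pair completing the tangent.
#'
#' @param m a [lumen_mask()] or [voxel_volume()].
#' @param point 3D position (voxel units) of the plane/grid center.
#' @param tangent unit plane normal.
#' @param half_extent half edge length of the sampled square, voxels.
#' @param spacing in-plane sample spacing, voxels.
#' @return an object of class `planar_slice` with elements `grid` (2D
#'   matrix), `axes` (list `u`, `v`), `origin`, `spacing`, `offsets`
#'   (in-plane sample coordinates).
#' @export
extract_slice <- function(m, point, tangent, half_extent, spacing = 1) {
  stopifnot(inherits(m, "voxel_volume"))
  tangent <- tangent / sqrt(sum(tangent^2))
  ax <- plane_axes(tangent)
  # symmetric in-plane grid about the origin (asymmetry would bias centroids)
  nh <- floor(half_extent / spacing)
  offs <- spacing * seq(-nh, nh)
  ng <- length(offs)
  uu <- rep(offs, times = ng)
  vv <- rep(offs, each = ng)
  pts <- cbind(point[1L] + uu * ax$u[1L] + vv * ax$v[1L],
               point[2L] + uu * ax$u[2L] + vv * ax$v[2L],
               point[3L] + uu * ax$u[3L] + vv * ax$v[3L])
  vals <- cpp_trilinear(as.numeric(m$data), dim(m$data), pts)
  structure(list(grid = matrix(vals, ng, ng), axes = ax, origin = point,
                 spacing = spacing, offsets = offs),
            class = "planar_slice")
}

#' Lumen center within a planar slice
#'
#' Thresholds the interpolated slice at 0.5, labels 8-connected foreground
#' components, selects the component containing (or nearest to) the
#' reference in-plane position, and returns the centroid of that component
#' mapped back to 3D. Samples interpolating to exactly 0.5 — the trilinear
#' midpoint of a binary edge — count half (midpoint rule), which removes
#' the quarter-voxel dilation a hard `>= 0.5` rule would give on
#' sub-voxel-spaced grids. Ties between equidistant components go to the
#' larger area. An empty slice signals a gap (`NULL`): the caller carries
#' the previous point forward.
#'
#' @param s a `planar_slice`.
#' @param reference in-plane 2D reference position (default the plane
#'   origin, `c(0, 0)`).
#' @return list with `point` (3D centroid), `area` (component sample count
#'   times spacing^2) and `inplane` (2D centroid), or `NULL` for an empty
#'   slice.
#' @export
slice_center <- function(s, reference = c(0, 0)) {
  eps <- 1e-9
  fg <- s$grid >= 0.5 - eps
  if (!any(fg)) return(NULL)
  w <- ifelse(s$grid > 0.5 + eps, 1, 0.5)   # midpoint-rule tie weight
  lab <- matrix(cpp_label2d(as.vector(fg), dim(fg)), nrow(fg), ncol(fg))
  ids <- seq_len(max(lab))
  uo <- s$offsets[row(fg)]; vo <- s$offsets[col(fg)]
  stats_ <- lapply(ids, function(i) {
    sel <- lab == i
    ws <- w[sel]
    cu <- sum(uo[sel] * ws) / sum(ws)
    cv <- sum(vo[sel] * ws) / sum(ws)
    # distance from the reference to the nearest pixel of the component
    dmin <- min((uo[sel] - reference[1L])^2 + (vo[sel] - reference[2L])^2)
    list(cu = cu, cv = cv, n = sum(ws), dmin = dmin)
  })
  dmins <- vapply(stats_, `[[`, numeric(1), "dmin")
  ns <- vapply(stats_, `[[`, numeric(1), "n")
  pick <- order(dmins, -ns)[1L]
  st <- stats_[[pick]]
  pt <- s$origin + st$cu * s$axes$u + st$cv * s$axes$v
  list(point = pt, area = st$n * s$spacing^2, inplane = c(st$cu, st$cv))
}

#' Relaxed centerline update
#'
#' Blends the recentered points with the previous iterate,
#' `c_new = (1 - beta) * c_recentered + beta * c_prev`, then Gaussian
#' smooths each coordinate sequence along the curve. The relaxation weight
#' beta stabilizes convergence on strongly non-cylindrical lumina
#' (beta = 0.5 by default; 0.9 for debris-contaminated masks).
#'
#' @param c_j recentered points, `n x 3`.
#' @param c_i previous iterate, `n x 3`.
#' @param beta relaxation parameter in `[0, 1)`.
#' @param sigma Gaussian smoothing width in samples (0 disables smoothing).
#' @return updated `n x 3` point matrix.
#' @export
relax_update <- function(c_j, c_i, beta, sigma = 0) {
  if (!all(dim(c_j) == dim(c_i)))
    stop("point sequences must have equal length")
  stopifnot(beta >= 0, beta < 1)
  smooth_points((1 - beta) * c_j + beta * c_i, sigma)
}

#' Centerline residual
#'
#' Mean Euclidean distance between corresponding points of two centerline
#' iterates, in voxel lengths:
#' `rho = sum_k d(c_prev[k], c_curr[k]) / N_k`.
#'
#' @param c_prev,c_curr `n x 3` point matrices of equal length.
#' @return the residual rho (voxel lengths).
#' @export
centerline_residual <- function(c_prev, c_curr) {
  if (!all(dim(c_prev) == dim(c_curr)))
    stop("centerlines must have equal numbers of points")
  mean(sqrt(rowSums((c_prev - c_curr)^2)))
}

# Extend a mask beyond the z faces by replicating the boundary slices: a
# vessel crossing the stack is assumed to continue, so orthogonal planes
# near the faces are not clipped against an artificial void.
pad_mask_z <- function(m, pad) {
  d <- dim(m$data)
  out <- array(0L, c(d[1L], d[2L], d[3L] + 2L * pad))
  out[, , pad + seq_len(d[3L])] <- m$data
  for (j in seq_len(pad)) {
    out[, , j] <- m$data[, , 1L]
    out[, , d[3L] + pad + j] <- m$data[, , d[3L]]
  }
  lumen_mask(out, m$voxel_length, m$name)
}

default_half_extent <- function(m) {
  # 1.5 x the largest per-z-slice foreground bounding-box half-diagonal,
  # so orthogonal sections never clip the lumen
  d <- dim(m$data)
  best <- 0
  for (z in seq_len(d[3L])) {
    sl <- m$data[, , z]
    if (!any(sl > 0L)) next
    xr <- range(which(rowSums(sl) > 0L))
    yr <- range(which(colSums(sl) > 0L))
    half <- sqrt((diff(xr) / 2)^2 + (diff(yr) / 2)^2)
    if (half > best) best <- half
  }
  max(3, 1.5 * best)
}

#' Fit the centerline of a segmented lumen
#'
#' The package's core estimator. Starting from smoothed per-slice
#' centroids, the centerline is iterated to a fixed point: tangents by
#' second-order finite differences, orthogonal-plane resampling by
#' trilinear interpolation, recentering on the nearest lumen component,
#' relaxation with weight `beta` and Gaussian smoothing with width `sigma`,
#' until the mean point displacement per iteration drops below `mu` voxel
#' lengths. The full residual history and all intermediate centerlines are
#' retained.
#'
#' Non-convergence within `max_iter` yields a warning, never an error; the
#' best-so-far centerline is returned with `converged = FALSE`.
#'
#' @param m a [lumen_mask()].
#' @param beta relaxation parameter in `[0, 1)` (default 0.5; use 0.9 for
#'   debris-contaminated masks).
#' @param sigma Gaussian smoothing width in samples along the curve
#'   (default 20).
#' @param mu convergence threshold on the residual, voxel lengths
#'   (default 0.3).
#' @param max_iter iteration cap (default 100).
#' @param half_extent half edge length of the orthogonal sampling grid in
#'   voxels; defaults to 1.5 x the largest per-slice bounding-box
#'   half-diagonal.
#' @param spacing in-plane sample spacing in voxels.
#' @return an object of class `centerline_fit` with components
#'   `points` (`n x 3`, final centerline, voxel units), `tangents`
#'   (`n x 3` unit vectors), `residuals` (residual per iteration),
#'   `iterations`, `converged`, `history` (list of per-iteration point
#'   matrices, starting at the initial centerline), `gaps` (indices carried
#'   forward at least once in the final iteration), and the call
#'   parameters.
#' @export
centerline_fit <- function(m, beta = 0.5, sigma = 20, mu = 0.3,
                           max_iter = 100L, half_extent = NULL,
                           spacing = 1) {
  stopifnot(inherits(m, "lumen_mask"),
            beta >= 0, beta < 1, sigma >= 0, mu > 0, max_iter >= 1L)
  if (!any(m$data > 0L)) stop("mask has no foreground voxels")
  if (is.null(half_extent)) half_extent <- default_half_extent(m)
  cur <- initial_centerline(m, sigma)
  n <- nrow(cur)
  # replicate the z faces so oblique planes near the stack ends see a
  # continued vessel instead of clipping against the volume boundary
  pad <- ceiling(half_extent)
  mp <- pad_mask_z(m, pad)
  zoff <- c(0, 0, pad)
  history <- list(cur)
  residuals <- numeric(0)
  converged <- FALSE
  iter <- 0L
  gaps <- integer(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    tau <- centerline_tangents(cur)
    cj <- cur
    gaps_i <- integer(0)
    for (k in seq_len(n)) {
      sl <- extract_slice(mp, cur[k, ] + zoff, tau[k, ], half_extent, spacing)
      ctr <- slice_center(sl)
      if (is.null(ctr)) {
        gaps_i <- c(gaps_i, k)        # gap: carry the previous point forward
      } else {
        cj[k, ] <- ctr$point - zoff
      }
    }
    nxt <- relax_update(cj, cur, beta, sigma)
    rho <- centerline_residual(cur, nxt)
    residuals <- c(residuals, rho)
    cur <- nxt
    history[[length(history) + 1L]] <- cur
    gaps <- gaps_i
    if (rho < mu) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("centerline did not converge in %d iterations (rho = %.3g)",
                    max_iter, residuals[length(residuals)]))
  structure(list(points = cur, tangents = centerline_tangents(cur),
                 residuals = residuals, iterations = iter,
                 converged = converged, history = history, gaps = gaps,
                 beta = beta, sigma = sigma, mu = mu, max_iter = max_iter,
                 half_extent = half_extent, spacing = spacing,
                 voxel_length = m$voxel_length),
            class = "centerline_fit")
}

#' @export
print.centerline_fit <- function(x, ...) {
  cat(sprintf("Centerline fit: %d points, %d iteration%s, %s\n",
              nrow(x$points), x$iterations,
              if (x$iterations == 1L) "" else "s",
              if (x$converged) sprintf("converged (rho = %.4f < mu = %g)",
                                       x$residuals[length(x$residuals)], x$mu)
              else sprintf("NOT converged (rho = %.4f >= mu = %g)",
                           x$residuals[length(x$residuals)], x$mu)))
  cat(sprintf("  beta = %g, sigma = %g, mu = %g voxel\n",
              x$beta, x$sigma, x$mu))
  invisible(x)
}

#' @export
summary.centerline_fit <- function(object, ...) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(object$points)^2))))
  out <- list(n_points = nrow(object$points),
              iterations = object$iterations,
              converged = object$converged,
              residuals = object$residuals,
              arclength_voxel = arc[length(arc)],
              arclength_mm = arc[length(arc)] * object$voxel_length * 1e-3,
              gaps = object$gaps,
              beta = object$beta, sigma = object$sigma, mu = object$mu)
  class(out) <- "summary.centerline_fit"
  out
}

#' @export
print.summary.centerline_fit <- function(x, ...) {
  cat(sprintf("Centerline of %d points over %.1f voxels (%.3f mm) arclength\n",
              x$n_points, x$arclength_voxel, x$arclength_mm))
  cat(sprintf("  %d iteration%s, %sconverged (beta = %g, sigma = %g, mu = %g)\n",
              x$iterations, if (x$iterations == 1L) "" else "s",
              if (x$converged) "" else "NOT ", x$beta, x$sigma, x$mu))
  cat("  residual history:", paste(sprintf("%.3f", x$residuals),
                                   collapse = " "), "\n")
  if (length(x$gaps))
    cat("  gap stations carried forward:", paste(x$gaps, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
residuals.centerline_fit <- function(object, ...) object$residuals

#' @export
coef.centerline_fit <- function(object, ...) {
  cbind(object$points, tx = object$tangents[, 1L],
        ty = object$tangents[, 2L], tz = object$tangents[, 3L])
}

#' Interpolate centerline points at arclength positions
#'
#' @param object a [centerline_fit()].
#' @param arclength positions along the curve in voxel units (default: the
#'   fitted stations).
#' @param ... unused.
#' @return matrix of 3D positions at the requested arclengths.
#' @export
predict.centerline_fit <- function(object, arclength = NULL, ...) {
  p <- object$points
  arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  if (is.null(arclength)) return(p)
  out <- vapply(seq_len(3L), function(j)
    stats::approx(arc, p[, j], xout = arclength, rule = 2L)$y,
    numeric(length(arclength)))
  matrix(out, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
}

#' Plot a centerline fit
#'
#' Left panel: residual convergence history on a log scale with the
#' threshold `mu`. Right panel: x and y coordinates of the final centerline
#' against z, with the initial centerline dashed.
#'
#' @param x a [centerline_fit()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.centerline_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$residuals), x$residuals, type = "b", log = "y",
                 xlab = "iteration", ylab = expression(rho ~ "(voxel)"),
                 main = "residual convergence", ...)
  graphics::abline(h = x$mu, lty = 2)
  p0 <- x$history[[1L]]
  p <- x$points
  rng <- range(p[, 1L], p[, 2L], p0[, 1L], p0[, 2L])
  graphics::plot(p[, 3L], p[, 1L], type = "l", col = "firebrick",
                 ylim = rng, xlab = "z (voxel)", ylab = "x, y (voxel)",
                 main = "centerline")
  graphics::lines(p[, 3L], p[, 2L], col = "steelblue")
  graphics::lines(p0[, 3L], p0[, 1L], col = "firebrick", lty = 3)
  graphics::lines(p0[, 3L], p0[, 2L], col = "steelblue", lty = 3)
  invisible(x)
}

#' Rebuild a centerline fit from its delimited-text record
#'
#' Reconstructs a minimal [centerline_fit()] object from the table written
#' by [write_centerline()] (columns `x, y, z` and optionally
#' `tx, ty, tz`), so a stored centerline can drive [area_profile()]
#' without refitting.
#'
#' @param table data frame or CSV path with the centerline record.
#' @param m the [lumen_mask()] the centerline belongs to (sets the slice
#'   half-extent and voxel length).
#' @return a `centerline_fit` object flagged as converged, with an empty
#'   residual history.
#' @export
centerline_from_table <- function(table, m) {
  if (is.character(table)) table <- utils::read.csv(table)
  stopifnot(all(c("x", "y", "z") %in% names(table)),
            inherits(m, "lumen_mask"))
  p <- as.matrix(table[, c("x", "y", "z")])
  tau <- if (all(c("tx", "ty", "tz") %in% names(table)))
    as.matrix(table[, c("tx", "ty", "tz")]) else centerline_tangents(p)
  structure(list(points = p, tangents = tau, residuals = numeric(0),
                 iterations = 0L, converged = TRUE, history = list(p),
                 gaps = integer(0), beta = NA_real_, sigma = NA_real_,
                 mu = NA_real_, max_iter = NA_integer_,
                 half_extent = default_half_extent(m), spacing = 1,
                 voxel_length = m$voxel_length),
            class = "centerline_fit")
}

#' Write a fitted centerline as delimited text
#'
#' Columns: `k, x, y, z, tx, ty, tz` (voxel units).
#'
#' @param fit a [centerline_fit()].
#' @param path output CSV path.
#' @param residuals_path optional path for the residual history.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(fit, path, residuals_path = NULL) {
  df <- data.frame(k = seq_len(nrow(fit$points)),
                   x = fit$points[, 1L], y = fit$points[, 2L],
                   z = fit$points[, 3L],
                   tx = fit$tangents[, 1L], ty = fit$tangents[, 2L],
                   tz = fit$tangents[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(residuals_path))
    utils::write.csv(data.frame(iteration = seq_along(fit$residuals),
                                rho = fit$residuals),
                     residuals_path, row.names = FALSE)
  invisible(path)
}
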