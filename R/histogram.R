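#' Joint histogram of two registered volumes
#'
#' Bins the voxel-wise intensity pairs of two pre-registered volumes on a
#' 2D grid. By default each axis spans the 1st-99th percentile of its
#' volume; intensities outside the range are clamped into the edge bins so
#' the total count equals the number of voxels and the marginals are
#' recovered exactly by row/column sums. Clusters in this histogram
#' correspond to tissue classes imaged by both modalities.
#'
#' @param a,b [voxel_volume()]s of identical grid shape.
#' @param n_bins bins per axis (default 256).
#' @param range_a,range_b optional explicit intensity ranges
#'   `c(lo, hi)` overriding the percentile rule.
#' @param probs percentile pair used for the default ranges.
#' @return an object of class `joint_histogram`: list with `counts`
#'   (`n_bins x n_bins`, A along rows), `edges_a`, `edges_b`, `n_voxels`.
#' @export
joint_histogram <- function(a, b, n_bins = 256L, range_a = NULL,
                            range_b = NULL, probs = c(0.01, 0.99)) {
  stopifnot(inherits(a, "voxel_volume"), inherits(b, "voxel_volume"))
  if (!all(dim(a$data) == dim(b$data)))
    stop("volumes must share the same grid shape (pre-registered inputs)")
  n_bins <- as.integer(n_bins)
  va <- as.vector(a$data); vb <- as.vector(b$data)
  if (is.null(range_a))
    range_a <- stats::quantile(va, probs, names = FALSE)
  if (is.null(range_b))
    range_b <- stats::quantile(vb, probs, names = FALSE)
  if (diff(range_a) <= 0) range_a <- range_a + c(-0.5, 0.5)
  if (diff(range_b) <= 0) range_b <- range_b + c(-0.5, 0.5)
  edges_a <- seq(range_a[1L], range_a[2L], length.out = n_bins + 1L)
  edges_b <- seq(range_b[1L], range_b[2L], length.out = n_bins + 1L)
  ia <- bin_index(va, edges_a)
  ib <- bin_index(vb, edges_b)
  counts <- matrix(tabulate(ia + (ib - 1L) * n_bins, n_bins * n_bins),
                   n_bins, n_bins)
  structure(list(counts = counts, edges_a = edges_a, edges_b = edges_b,
                 n_voxels = length(va)),
            class = "joint_histogram")
}

bin_index <- function(x, edges) {
  n <- length(edges) - 1L
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), n)  # clamp out-of-range values into the edge bins
}

#' Marginal 1D histogram of a volume
#'
#' Same binning and clamping rules as [joint_histogram()], so the result
#' matches the corresponding joint-histogram marginal bin-for-bin.
#'
#' @param v a [voxel_volume()].
#' @param n_bins number of bins.
#' @param range optional explicit `c(lo, hi)` range.
#' @param probs percentile pair for the default range.
#' @return list with `counts`, `edges`, `mids`.
#' @export
intensity_histogram <- function(v, n_bins = 256L, range = NULL,
                                probs = c(0.01, 0.99)) {
  stopifnot(inherits(v, "voxel_volume"))
  x <- as.vector(v$data)
  if (is.null(range)) range <- stats::quantile(x, probs, names = FALSE)
  if (diff(range) <= 0) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  counts <- tabulate(bin_index(x, edges), n_bins)
  list(counts = counts, edges = edges,
       mids = (edges[-1L] + edges[-length(edges)]) / 2)
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("Joint histogram: %d x %d bins over %d voxels\n",
              nrow(x$counts), ncol(x$counts), x$n_voxels))
  invisible(x)
}

#' Plot a joint histogram on a log scale
#'
#' Displays `log10(1 + count)` as an image, the standard rendering that
#' handles empty bins.
#'
#' @param x a `joint_histogram`.
#' @param ... passed to [graphics::image()].
#' @export
plot.joint_histogram <- function(x, ...) {
  mids_a <- (x$edges_a[-1L] + x$edges_a[-length(x$edges_a)]) / 2
  mids_b <- (x$edges_b[-1L] + x$edges_b[-length(x$edges_b)]) / 2
  graphics::image(mids_a, mids_b, log10(1 + x$counts),
                  xlab = "intensity A", ylab = "intensity B",
                  main = "joint histogram (log10(1 + count))", ...)
  invisible(x)
}

#' Fit a sum of Gaussians to a binned histogram
#'
#' Least-squares fit of `sum_i a_i exp(-(x - m_i)^2 / (2 s_i^2))` to
#' histogram counts versus bin centers, by Levenberg-Marquardt with
#' positivity bounds on amplitudes and widths. This fits curves to
#' histogram peaks (four peaks correspond to embedding paraffin, fibrous
#' tissue, vessel wall and residual plaque); it is not a latent-variable
#' EM mixture fit. Default initialization takes the `n_components` highest
#' well-separated local maxima. Solver non-convergence is flagged, with the
#' best-so-far parameters returned.
#'
#' @param h a histogram as returned by [intensity_histogram()] (list with
#'   `counts` and `mids`), or a numeric vector of counts (bin centers then
#'   default to `seq_along(counts)`).
#' @param n_components number of Gaussian components (default 4).
#' @param init optional `n x 3` matrix of starting `(amplitude, mean,
#'   sigma)` triples.
#' @return an object of class `gaussian_mixture_fit`: list with
#'   `components` (data frame `amplitude, mean, sigma`, sorted by mean),
#'   `n_components`, `rss`, `converged`, `fitted`.
#' @export
fit_multi_gaussian <- function(h, n_components = 4L, init = NULL) {
  if (is.numeric(h)) h <- list(counts = h, mids = seq_along(h))
  counts <- as.numeric(h$counts)
  mids <- as.numeric(h$mids)
  n_components <- as.integer(n_components)
  stopifnot(n_components >= 1L, length(counts) == length(mids))
  if (sum(counts > 0) < 3L * n_components)
    stop("histogram needs at least 3 nonzero bins per component")
  bw <- stats::median(diff(mids))
  if (is.null(init)) init <- init_peaks(counts, mids, n_components)
  model <- function(par, x) {
    y <- numeric(length(x))
    for (i in seq_len(n_components)) {
      a <- par[3 * i - 2]; mu <- par[3 * i - 1]; s <- par[3 * i]
      y <- y + a * exp(-0.5 * ((x - mu) / s)^2)
    }
    y
  }
  par0 <- as.vector(t(init))
  lower <- rep(c(0, min(mids) - 10 * bw, bw / 4), n_components)
  upper <- rep(c(Inf, max(mids) + 10 * bw, diff(range(mids))), n_components)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0,
                       fn = function(p) counts - model(p, mids),
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    par <- par0
    converged <- FALSE
  } else {
    par <- fit$par
    converged <- fit$info %in% 1:4
  }
  comp <- data.frame(amplitude = par[seq(1, by = 3, length.out = n_components)],
                     mean = par[seq(2, by = 3, length.out = n_components)],
                     sigma = par[seq(3, by = 3, length.out = n_components)])
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  fitted <- model(par, mids)
  structure(list(components = comp, n_components = n_components,
                 rss = sum((counts - fitted)^2), converged = converged,
                 fitted = fitted, mids = mids, counts = counts),
            class = "gaussian_mixture_fit")
}

# the n highest local maxima separated by at least n_bins/(2 n) bins
init_peaks <- function(counts, mids, n_components) {
  nb <- length(counts)
  sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  sm <- as.numeric(sm)
  is_max <- c(FALSE, diff(sign(diff(sm))) < 0, FALSE) & counts > 0
  cand <- which(is_max)
  if (!length(cand)) cand <- which.max(counts)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  min_sep <- max(2L, floor(nb / (2L * n_components)))
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
    if (length(keep) == n_components) break
  }
  if (length(keep) < n_components) {
    # fall back to quantile-spaced positions for the remainder
    extra <- round(seq(1, nb, length.out = n_components + 2L))[-c(1, n_components + 2L)]
    for (i in extra) {
      if (length(keep) == n_components) break
      if (all(abs(i - keep) >= min_sep %/% 2L)) keep <- c(keep, i)
    }
    while (length(keep) < n_components)
      keep <- c(keep, sample.int(nb, 1L))
  }
  bw <- stats::median(diff(mids))
  cbind(amplitude = pmax(counts[keep], 1),
        mean = mids[keep],
        sigma = rep(min_sep * bw / 2, length(keep)))
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("Multi-Gaussian fit: %d components, rss = %.4g%s\n",
              x$n_components, x$rss,
              if (x$converged) "" else " (solver did not converge)"))
  print(x$components, digits = 4)
  invisible(x)
}

#' @export
plot.gaussian_mixture_fit <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h", col = "gray70",
                 xlab = "intensity", ylab = "count",
                 main = "histogram and multi-Gaussian fit", ...)
  graphics::lines(x$mids, x$fitted, col = "goldenrod", lwd = 2)
  invisible(x)
}

#' Isotropic Gaussian prefilter
#'
#' Separable 3D Gaussian convolution (edge-replicating borders). The mean
#' intensity is preserved to numerical precision; on noisy
#' piecewise-constant data it sharpens histogram peaks that would
#' otherwise overlap (the effect exploited to make four tissue peaks
#' separable in a noisy modality).
#'
#' @param v a [voxel_volume()].
#' @param sigma Gaussian standard deviation in voxels (default 2).
#' @return a filtered [voxel_volume()].
#' @export
gaussian_prefilter <- function(v, sigma = 2) {
  stopifnot(inherits(v, "voxel_volume"), sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(v$data)
  out <- as.numeric(v$data)
  for (axis in 0:2) out <- cpp_conv_axis(out, d, k, axis)
  voxel_volume(array(out, d), v$voxel_length, v$name)
}

#' Count separable peaks in a histogram
#'
#' Local maxima of the (lightly smoothed) count sequence that are
#' prominent: each reported peak rises by at least `min_prominence_frac`
#' of the tallest count above the highest valley separating it from
#' larger peaks. Prominence, rather than raw height, distinguishes
#' genuinely separable tissue-class peaks from counting-noise undulations
#' on a broad merged hump.
#'
#' @param h histogram (as [intensity_histogram()]) or a counts vector.
#' @param min_prominence_frac minimum prominence as a fraction of the
#'   maximum count.
#' @param min_sep minimum separation between reported peaks, bins.
#' @param smooth boxcar half-width applied before peak picking.
#' @return integer vector of peak bin indices.
#' @export
find_peaks <- function(h, min_prominence_frac = 0.05, min_sep = 5L,
                       smooth = 2L) {
  counts <- if (is.list(h)) as.numeric(h$counts) else as.numeric(h)
  n <- length(counts)
  if (smooth > 0L) {
    w <- 2L * smooth + 1L
    sm <- stats::filter(counts, rep(1 / w, w), sides = 2)
    sm[is.na(sm)] <- counts[is.na(sm)]
    counts <- as.numeric(sm)
  }
  is_max <- c(FALSE, diff(sign(diff(counts))) < 0, FALSE)
  cand <- which(is_max)
  if (!length(cand)) cand <- which.max(counts)
  prom <- vapply(cand, function(i) {
    # walk to the nearest strictly higher sample on each side; the peak's
    # prominence is its height above the higher of the two lowest valleys
    higher_l <- which(counts[seq_len(i - 1L)] > counts[i])
    higher_r <- which(counts[seq(i + 1L, length.out = n - i)] > counts[i]) + i
    vall <- if (length(higher_l)) min(counts[max(higher_l):i]) else min(counts[1:i])
    valr <- if (length(higher_r)) min(counts[i:min(higher_r)]) else min(counts[i:n])
    counts[i] - max(vall, valr)
  }, numeric(1))
  keep_c <- cand[prom >= min_prominence_frac * max(counts)]
  keep_c <- keep_c[order(counts[keep_c], decreasing = TRUE)]
  keep <- integer(0)
  for (i in keep_c) if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  sort(keep)
}
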