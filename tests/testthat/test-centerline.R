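test_that("initial centerline reproduces slice centroids", {
  ph <- phantom_preset("straight")
  p0 <- initial_centerline(ph$mask, 20)
  expect_equal(p0[, 1L], rep(22, 80))
  expect_equal(p0[, 2L], rep(22, 80))
  expect_equal(p0[, 3L], 1:80)

  # degenerate smoothing returns the raw centroids
  m <- array(0L, c(6, 6, 3))
  m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L; m[3, 3, 3] <- 1L
  p <- initial_centerline(lumen_mask(m), 0)
  expect_equal(p, cbind(x = 1:3, y = 1:3, z = 1:3))

  expect_error(initial_centerline(lumen_mask(array(0L, c(4, 4, 4))[, , 1,
                                                                   drop = FALSE])),
               "3 z-slices|foreground")
})

test_that("initial centerline tracks a tilted axis within half a voxel", {
  ob <- make_oblique_cylinder(30, 10, c(88, 44, 88))
  p0 <- initial_centerline(ob$mask, 20)
  devs <- dist_to_truth(p0, ob$truth)
  expect_lt(max(devs), 0.5)
})

test_that("tangents match second-order stencils exactly on polynomials", {
  # straight line
  line <- cbind(0, 0, 1:10)
  tau <- centerline_tangents(line)
  expect_equal(tau, matrix(rep(c(0, 0, 1), each = 10), 10),
               ignore_attr = TRUE)

  # quadratic curve: central and one-sided stencils are exact
  k <- 0:8
  quad <- cbind(2 + 0.5 * k - 0.03 * k^2, -1 + 0.2 * k + 0.01 * k^2, k)
  tau <- centerline_tangents(quad)
  dtrue <- cbind(0.5 - 0.06 * k, 0.2 + 0.02 * k, 1)
  dtrue <- dtrue / sqrt(rowSums(dtrue^2))
  expect_equal(tau, dtrue, tolerance = 1e-12, ignore_attr = TRUE)

  # explicit endpoint stencil (-3 f0 + 4 f1 - f2) / 2
  three <- cbind(c(0, 1, 4), 0, c(0, 2, 3))
  tau3 <- centerline_tangents(three)
  v <- c((-3 * 0 + 4 * 1 - 4) / 2, 0, (-3 * 0 + 4 * 2 - 3) / 2)
  expect_equal(tau3[1L, ], v / sqrt(sum(v^2)), tolerance = 1e-12)

  # dense circle samples: tangent orthogonal to the radius vector
  th <- seq(0, pi, length.out = 200)
  circ <- cbind(10 * cos(th), 0, 10 * sin(th))
  tauc <- centerline_tangents(circ)
  dots <- abs(rowSums(tauc * circ / 10))[2:199]
  expect_lt(max(dots), 1e-3)
})

test_that("slice extraction degenerates to stored slices on axis-aligned planes", {
  ph <- phantom_preset("straight")
  sl <- extract_slice(ph$mask, c(22, 22, 40), c(0, 0, 1), 21, 1)
  stored <- ph$mask$data[, , 40]
  # the sampled grid covers x,y in 1..43; compare the overlap
  expect_equal(sl$grid, stored[1:43, 1:43] * 1.0, ignore_attr = TRUE)
  expect_equal(sum(sl$grid >= 0.5), sum(stored))
})

test_that("orthogonal slices of an oblique cylinder have circular area", {
  ob <- make_oblique_cylinder(30, 10, c(88, 44, 88))
  axis_dir <- c(sin(pi / 6), 0, cos(pi / 6))
  mid <- as.numeric(ob$truth[which.min(abs(ob$truth$z - 44)),
                             c("x", "y", "z")])
  sl <- extract_slice(ob$mask, mid, axis_dir, 16, 1)
  area <- sum(sl$grid >= 0.5)
  expect_lt(abs(area / (pi * 100) - 1), 0.05)
  # naive z-slice through the same point is 1/cos(30 deg) larger
  zsl <- sum(ob$mask$data[, , round(mid[3L])])
  expect_gt(zsl / area, 1.10)
})

test_that("slice_center picks the component nearest the reference", {
  ph <- phantom_preset("straight")
  sl <- extract_slice(ph$mask, c(22, 22, 40), c(0, 0, 1), 21, 1)
  ctr <- slice_center(sl)
  expect_equal(ctr$point, c(22, 22, 40), tolerance = 1e-9,
               ignore_attr = TRUE)

  # two discs in one plane: centroid of the referenced one only
  d <- c(60L, 30L, 9L)
  xi <- seq_len(d[1L]); yi <- seq_len(d[2L])
  discs <- array(outer((xi - 15)^2, (yi - 15)^2, "+") <= 36 |
                   outer((xi - 45)^2, (yi - 15)^2, "+") <= 25, d)
  m <- lumen_mask(array(as.integer(discs), d))
  sl2 <- extract_slice(m, c(15, 15, 5), c(0, 0, 1), 25, 1)
  ctr2 <- slice_center(sl2)
  expect_equal(ctr2$point, c(15, 15, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(ctr2$area, sum(outer((xi - 15)^2, (yi - 15)^2, "+") <= 36))

  # an empty plane signals a gap
  sl3 <- extract_slice(m, c(15, 15, 5) * 0 + c(2, 28, 5), c(0, 0, 1), 1, 1)
  expect_null(slice_center(sl3))
})

test_that("relaxed update blends, smooths and validates", {
  cj <- cbind(c(2, 2, 2), 0, 1:3)
  ci <- cbind(0, 0, 1:3)
  expect_equal(relax_update(cj, ci, 0, sigma = 0), cj, ignore_attr = TRUE)
  expect_equal(relax_update(cj, ci, 0.5, sigma = 0)[, 1L], c(1, 1, 1))
  # beta = 0.9, the setting for debris-contaminated masks
  expect_equal(relax_update(cj, ci, 0.9, sigma = 0)[, 1L], c(0.2, 0.2, 0.2))
  expect_error(relax_update(cj[1:2, ], ci, 0.5), "equal")
})

test_that("gaussian curve smoothing preserves linear sequences", {
  x <- 3 + 0.7 * (1:50)
  expect_equal(gauss_smooth1d(x, 8), x)
  expect_equal(gauss_smooth1d(rep(2, 30), 5), rep(2, 30))
})

test_that("residual is the mean point-wise displacement", {
  a <- cbind(0, 0, 1:5)
  expect_equal(centerline_residual(a, a), 0)
  expect_equal(centerline_residual(a, a + matrix(rep(c(1, 0, 0), 5), 5,
                                                 byrow = TRUE)), 1)
  p1 <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  p2 <- rbind(c(1, 0, 0), c(0, 2, 1), c(0, 0, 2))
  expect_equal(centerline_residual(p1, p2), 1)
  expect_error(centerline_residual(p1, p2[1:2, ]), "equal")
})

test_that("a z-parallel lumen converges at the first residual check", {
  ph <- phantom_preset("straight")
  fit <- centerline_fit(ph$mask)
  expect_s3_class(fit, "centerline_fit")
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  axis_dev <- sqrt((fit$points[, 1L] - 22)^2 + (fit$points[, 2L] - 22)^2)
  expect_lt(max(axis_dev), 0.5)
})

test_that("bent phantom converges with non-increasing residuals", {
  ph <- phantom_preset("bent")
  fit <- centerline_fit(ph$mask)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 50L)
  if (length(fit$residuals) > 2L)
    expect_true(all(diff(fit$residuals[-1L]) <= 1e-9))
  expect_lt(rmse_to_truth(fit$points, ph$truth), 1)
  # every fitted point sits inside the lumen
  idx <- pmax(round(fit$points), 1)
  idx[, 1L] <- pmin(idx[, 1L], dim(ph$mask)[1L])
  idx[, 2L] <- pmin(idx[, 2L], dim(ph$mask)[2L])
  idx[, 3L] <- pmin(idx[, 3L], dim(ph$mask)[3L])
  expect_true(all(ph$mask$data[idx] == 1L))
})

test_that("centerline extraction is equivariant under 90-degree rotation", {
  ph <- phantom_preset("bent")
  fit <- centerline_fit(ph$mask)
  d <- dim(ph$mask)
  rot <- aperm(ph$mask$data, c(2, 1, 3))[rev(seq_len(d[2L])), , ]
  fit_r <- centerline_fit(lumen_mask(rot))
  # (x, y, z) -> (ny + 1 - y, x, z)
  mapped <- cbind(d[2L] + 1 - fit$points[, 2L], fit$points[, 1L],
                  fit$points[, 3L])
  expect_lt(max(sqrt(rowSums((fit_r$points - mapped)^2))), 0.5)
})

test_that("non-convergence warns and flags instead of failing", {
  ph <- phantom_preset("bent")
  expect_warning(fit <- centerline_fit(ph$mask, mu = 1e-6, max_iter = 2L),
                 "converge")
  expect_false(fit$converged)
  expect_length(fit$residuals, 2L)
})

test_that("fit methods expose the expected summaries", {
  ph <- phantom_preset("straight")
  fit <- centerline_fit(ph$mask)
  expect_output(print(fit), "converged")
  s <- summary(fit)
  expect_equal(s$n_points, 80L)
  expect_output(print(s), "residual history")
  expect_equal(residuals(fit), fit$residuals)
  co <- coef(fit)
  expect_equal(dim(co), c(80L, 6L))
  pr <- predict(fit, arclength = c(0, 10, 79))
  expect_equal(pr[, "z"], c(1, 11, 80), tolerance = 1e-8)
  tf <- tempfile(fileext = ".csv")
  write_centerline(fit, tf)
  expect_equal(nrow(utils::read.csv(tf)), 80L)
})
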