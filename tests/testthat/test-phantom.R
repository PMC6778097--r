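test_that("tube rasterization matches the exhaustive capsule oracle", {
  dims <- c(28L, 28L, 16L)
  pts <- rbind(c(14, 14, 1), c(14, 14, 16))
  spec <- tube_spec(pts, 6, dims)
  tube <- make_tube(spec)
  oracle <- oracle_tube_mask(pts, c(6, 6), dims)
  expect_identical(tube$mask$data == 1L, oracle)

  # bent tube with varying radius against the same oracle
  curve <- function(t) cbind(10 + 6 * t, 14 + 3 * sin(pi * t), 1 + 30 * t)
  spec2 <- tube_spec(curve, function(t) 4 + 2 * t, c(32L, 28L, 31L))
  tube2 <- make_tube(spec2, n_samples = 129L)
  t2 <- seq(0, 1, length.out = 129L)
  oracle2 <- oracle_tube_mask(curve(t2), 4 + 2 * t2, c(32L, 28L, 31L))
  expect_identical(tube2$mask$data == 1L, oracle2)
})

test_that("straight tube slices are exact lattice discs with analytic truth", {
  ph <- phantom_preset("straight")
  xi <- seq_len(dim(ph$mask)[1L])
  disc <- sum(outer((xi - 22)^2, (xi - 22)^2, "+") <= 100)
  perz <- apply(ph$mask$data, 3L, sum)
  expect_true(all(perz == disc))
  expect_equal(ph$truth$area, rep(pi * 100, nrow(ph$truth)))
  expect_true(all(diff(ph$truth$arclength) > 0))
})

test_that("rasterized per-station area converges to pi r^2 as r grows", {
  for (r in c(8, 10, 14)) {
    dims <- c(2L * r + 12L, 2L * r + 12L, 10L)
    cx <- (dims[1L] + 1) / 2
    spec <- tube_spec(rbind(c(cx, cx, 1), c(cx, cx, 10)), r, dims)
    tube <- make_tube(spec)
    perz <- apply(tube$mask$data, 3L, sum)
    expect_lt(max(abs(perz / (pi * r^2) - 1)), 0.05)
  }
})

test_that("ground-truth centerline points are foreground voxels", {
  for (preset in c("straight", "bent", "swelling-benchmark", "bifurcation")) {
    ph <- phantom_preset(preset)
    idx <- round(as.matrix(ph$truth[, c("x", "y", "z")]))
    vals <- ph$mask$data[idx]
    expect_true(all(vals == 1L), label = paste(preset, "centerline inside"))
  }
})

test_that("oblique cylinder has angle-independent orthogonal truth", {
  ob0 <- make_oblique_cylinder(0, 10, c(44, 44, 40))
  cx <- (44 + 1) / 2
  straight <- make_tube(tube_spec(rbind(c(cx, cx, 1), c(cx, cx, 40)), 10,
                                  c(44L, 44L, 40L)))
  expect_identical(ob0$mask$data, straight$mask$data)

  ob45 <- make_oblique_cylinder(45, 8, c(72, 40, 40))
  expect_equal(ob45$truth$area, rep(pi * 64, nrow(ob45$truth)))

  # per-z foreground counts inflate like 1/cos(angle)
  ob30 <- make_oblique_cylinder(30, 10, c(88, 44, 88))
  perz <- apply(ob30$mask$data, 3L, sum)
  inner <- perz[15:74]
  expect_lt(abs(mean(inner) / (pi * 100 / cos(pi / 6)) - 1), 0.02)
})

test_that("tube and branch specs reject invalid geometry", {
  expect_error(tube_spec(rbind(c(10, 10, 1), c(10, 10, 20)), 1.5,
                         c(32, 32, 20)), ">= 2")
  expect_error(tube_spec(rbind(c(4, 16, 1), c(4, 16, 20)), 8, c(32, 32, 20)),
               "exits the grid")
  expect_error(branch_spec(0, c(1, 0, 0), 10, 3))
  expect_error(tube_spec(rbind(c(16, 16, 1), c(16, 16, 20)), 4,
                         c(32, 32, 20),
                         branch = branch_spec(0.5, c(1, 0, 0), 10, 5)),
               "exceeds parent")
})

test_that("two-modality phantom is deterministic and class-faithful", {
  cm <- slab_class_map(c(16L, 16L, 16L))
  means <- c(0, 30, 60, 90)
  a1 <- make_two_modality_phantom(cm, means, rep(4, 4), means, rep(4, 4),
                                  seed = 5)
  a2 <- make_two_modality_phantom(cm, means, rep(4, 4), means, rep(4, 4),
                                  seed = 5)
  expect_identical(a1$A$data, a2$A$data)
  expect_identical(a1$B$data, a2$B$data)

  # degenerate noise: piecewise-constant relabeling of the class map
  tiny <- make_two_modality_phantom(cm, means, rep(1e-9, 4), means,
                                    rep(1e-9, 4), seed = 1)
  expect_equal(tiny$A$data, array(means[cm], dim(cm)), tolerance = 1e-6)

  # voxel-wise coupled noise concentrates the joint histogram near the
  # diagonal when both modalities share parameters
  co <- make_two_modality_phantom(cm, means, rep(4, 4), means, rep(4, 4),
                                  seed = 5, noise_correlation = 1)
  expect_identical(co$A$data, co$B$data)

  expect_error(make_two_modality_phantom(array(1L, c(4, 4, 4)), means,
                                         rep(1, 4), means, rep(1, 4), 1),
               "labels")
})

test_that("class proportions of the label map are honored by construction", {
  dims <- c(32L, 32L, 20L)
  n <- prod(dims)
  labs <- rep(1:4, times = round(n * c(0.4, 0.3, 0.2, 0.1)))
  cm <- array(labs[seq_len(n)], dims)
  ph <- make_two_modality_phantom(cm, c(0, 10, 20, 30), rep(0.5, 4),
                                  c(0, 10, 20, 30), rep(0.5, 4), seed = 9)
  # class masses in the intensity histogram match the label proportions
  # within 3 binomial sigmas (classes are 10 sigma apart, so assignment by
  # nearest mean is essentially exact)
  assigned <- round(ph$A$data / 10) + 1
  for (k in 1:4) {
    pk <- sum(cm == k) / n
    tol <- 3 * sqrt(n * pk * (1 - pk))
    expect_lt(abs(sum(assigned == k) - sum(cm == k)), tol + 1)
  }
})

test_that("shrinkage pair encodes the prescribed segmental area ratios", {
  sp <- make_shrinkage_pair()
  expect_equal(sp$offset_mm, 0.5)
  # analytic radii: after = before * sqrt(scaling) inside each segment
  tb <- sp$before$truth
  ta <- sp$after$truth
  for (i in 1:3) {
    w <- sp$eval_windows[i, ]
    zb <- (w[1L] + w[2L]) / 2
    rb <- tb$r[which.min(abs(tb$z - zb))]
    ra <- ta$r[which.min(abs(ta$z - (zb - 50)))]
    expect_equal((ra / rb)^2, sp$scalings[i], tolerance = 1e-6)
  }
})
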