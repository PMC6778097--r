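test_that("median filter matches the brute-force neighborhood oracle", {
  set.seed(11)
  a <- array(sample(0:9, 12^3, TRUE), c(12, 12, 12))
  v <- voxel_volume(a)
  for (k in c(3L, 5L)) {
    expect_equal(median_smooth(v, k)$data, oracle_median3d(a, k),
                 ignore_attr = TRUE)
  }
})

test_that("median filter basics: constants, outliers, kernel validation", {
  const <- voxel_volume(array(3.7, c(6, 6, 6)))
  expect_equal(median_smooth(const, 3)$data, const$data)

  spike <- array(0, c(7, 7, 7)); spike[4, 4, 4] <- 100
  sm <- median_smooth(voxel_volume(spike), 3)
  expect_equal(max(sm$data), 0)

  expect_error(median_smooth(const, 4), "odd")
})

test_that("median filter is idempotent on a large convex binary tube", {
  ph <- phantom_preset("straight")
  v <- voxel_volume(ph$mask$data * 1.0)
  m1 <- median_smooth(v, 3)
  m2 <- median_smooth(m1, 3)
  expect_identical(m1$data, m2$data)
})

test_that("kernel-15 median shifts a soft-edged lumen boundary by <= 1 voxel", {
  # dark lumen in a bright wall with a 2-voxel linear edge: the smoothing
  # relocates the half-maximum boundary by at most one voxel (the shift
  # direction follows the boundary curvature; it vanishes on a flat edge)
  d <- c(96L, 96L, 31L)
  xi <- seq_len(d[1L])
  rad <- sqrt(outer((xi - 48)^2, (xi - 48)^2, "+"))
  wall <- pmin(1, pmax(0, (rad - 39) / 2))      # 0 inside lumen r=40
  v <- voxel_volume(array(rep(wall, d[3L]), d))
  vm <- median_smooth(v, 15)
  r_eff <- function(x) sqrt(sum(x$data[, , 16] < 0.5) / pi)
  shift <- r_eff(vm) - r_eff(v)
  expect_lte(abs(shift), 1)
})

test_that("region growing follows connectivity and tolerance", {
  ph <- phantom_preset("straight")
  binv <- voxel_volume(ph$mask$data * 1.0)
  g <- region_grow(binv, c(22, 22, 40), 0.5)
  expect_identical(g$data, ph$mask$data)

  # two disjoint tubes: only the seeded one is grown
  d <- c(40L, 20L, 20L)
  xi <- seq_len(d[1L]); yi <- seq_len(d[2L])
  t1 <- array(outer((xi - 10)^2, (yi - 10)^2, "+") <= 16, d)
  t2 <- array(outer((xi - 30)^2, (yi - 10)^2, "+") <= 16, d)
  v2 <- voxel_volume((t1 | t2) * 1.0)
  g2 <- region_grow(v2, c(10, 10, 10), 0.5)
  expect_true(all(g2$data[t2] == 0L))
  expect_true(all(g2$data[t1] == 1L))

  # additive uniform noise within the tolerance changes nothing
  set.seed(21)
  noisy <- voxel_volume(ph$mask$data +
                          array(runif(length(ph$mask$data), -0.1, 0.1),
                                dim(ph$mask$data)))
  gn <- region_grow(noisy, c(22, 22, 40), 0.3)
  expect_identical(gn$data, ph$mask$data)

  expect_error(region_grow(binv, c(100, 1, 1), 0.5), "outside")
})

test_that("ball opening matches the brute-force oracle on a small grid", {
  set.seed(31)
  d <- c(18L, 18L, 18L)
  xi <- seq_len(d[1L])
  fg <- array(outer(outer((xi - 9)^2, (xi - 9)^2, "+"), (xi - 9)^2, "+") <= 36,
              d)
  fg[13:15, 13:15, 9] <- TRUE   # attached lump thinner than the ball
  m <- lumen_mask(array(as.integer(fg), d))
  opened <- morph_open(m, 4)
  expect_identical(opened$data == 1L, oracle_open(fg, 4))
})

test_that("opening removes debris, keeps the vessel, and never adds voxels", {
  fx <- debris_cylinder()
  opened <- morph_open(fx$mask, 20)
  expect_true(all(opened$data <= fx$mask$data))

  # the protruding debris blob is erased ...
  out <- which(opened$data == 1L & !fx$cyl, arr.ind = TRUE)
  if (nrow(out)) {
    radial <- sqrt((out[, 1L] - 40)^2 + (out[, 2L] - 32)^2)
    expect_lt(max(radial), 25.5)
  }
  # ... while the cylinder core away from the end faces is retained
  xi <- seq_len(fx$dims[1L]); yi <- seq_len(fx$dims[2L])
  core <- array(outer((xi - 40)^2, (yi - 32)^2, "+") <= 24^2, fx$dims)
  core[, , c(1:21, 44:64)] <- FALSE
  expect_true(all(opened$data[core] == 1L))

  # radius 0 is the identity
  expect_identical(morph_open(fx$mask, 0)$data, fx$mask$data)
})

test_that("opening annihilates structures thinner than the ball", {
  d <- c(48L, 48L, 40L)
  xi <- seq_len(d[1L])
  cyl <- array(outer((xi - 24)^2, (xi - 24)^2, "+") <= 225, d)
  m <- lumen_mask(array(as.integer(cyl), d))
  expect_equal(sum(morph_open(m, 20)$data), 0)
})

test_that("the full segmentation chain reproduces a noisy tube", {
  ph <- phantom_preset("straight")
  set.seed(41)
  noisy <- voxel_volume(ph$mask$data +
                          array(runif(length(ph$mask$data), -0.1, 0.1),
                                dim(ph$mask$data)))
  params <- segmentation_params(median_kernel = 3L, grow_tolerance = 0.3,
                                seeds = matrix(c(22, 22, 40), 1))
  seg <- segment_lumen(noisy, params)
  agree <- mean(seg$data == ph$mask$data)
  expect_gt(agree, 0.995)
  expect_error(segment_lumen(noisy, segmentation_params()), "seed")
})
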