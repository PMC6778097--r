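test_that("straight-tube area profile is flat at pi r^2 in physical units", {
  ph <- phantom_preset("straight", voxel_length = 1.3)
  fit <- centerline_fit(ph$mask)
  prof <- area_profile(ph$mask, fit)
  expect_s3_class(prof, "cross_section_profile")
  expect_false(any(prof$gap))
  a_vox <- attr(prof, "area_voxel2")
  expect_lt(max(abs(a_vox / (pi * 100) - 1)), 0.05)
  # mm^2 conversion with the 1.3 um voxel of the high-resolution setup
  expect_equal(prof$area_mm2, a_vox * (1.3e-3)^2)
  s_vox <- attr(prof, "station_voxel")
  expect_equal(prof$station_mm, s_vox * 1.3e-3)
  expect_true(all(diff(prof$station_mm) > 0))
})

test_that("area scales with the square of the voxel length", {
  ph <- phantom_preset("straight")
  fit <- centerline_fit(ph$mask)
  p1 <- area_profile(ph$mask, fit, voxel_length = 2)
  p2 <- area_profile(ph$mask, fit, voxel_length = 4)
  expect_equal(p2$area_mm2, 4 * p1$area_mm2)
  expect_equal(p2$station_mm, 2 * p1$station_mm)
})

test_that("swelling benchmark areas follow the canal-section truth", {
  ph <- phantom_preset("swelling-benchmark")
  fit <- centerline_fit(ph$mask)
  prof <- area_profile(ph$mask, fit)
  a <- attr(prof, "area_voxel2")
  tr <- ph$truth
  idx <- apply(fit$points, 1L, function(p)
    which.min(colSums((t(as.matrix(tr[, c("x", "y", "z")])) - p)^2)))
  rel <- a / tr$area_section[idx] - 1
  n <- length(rel)
  interior <- seq_len(n) > 15 & seq_len(n) < n - 15
  sel <- interior & tr$r[idx] >= 8
  expect_lt(max(abs(rel[sel])), 0.05)
})

test_that("orthogonal profiling discounts the oblique per-slice inflation", {
  ob <- make_oblique_cylinder(30, 10, c(88, 44, 88))
  fit <- centerline_fit(ob$mask)
  prof <- area_profile(ob$mask, fit)
  a <- attr(prof, "area_voxel2")
  n <- length(a)
  interior <- seq_len(n) > 12 & seq_len(n) < n - 12
  expect_lt(max(abs(a[interior] / (pi * 100) - 1)), 0.05)
  perz <- apply(ob$mask$data, 3L, sum)
  ratio <- mean(perz[15:74]) / mean(a[interior])
  expect_lt(abs(ratio / (1 / cos(pi / 6)) - 1), 0.02)
})

test_that("profile alignment recovers constructed shifts", {
  ph <- phantom_preset("swelling-benchmark", voxel_length = 10)
  fit <- centerline_fit(ph$mask)
  prof <- area_profile(ph$mask, fit)
  expect_lt(abs(align_profiles(prof, prof)), 1e-3)

  shifted <- prof
  shifted$station_mm <- shifted$station_mm + 0.5
  # b's stations sit 0.5 mm high: shifting them by -0.5 lands on a
  off <- align_profiles(prof, shifted)
  expect_lt(abs(off + 0.5), 0.011)

  flat <- prof
  flat$area_mm2 <- rep(1, nrow(flat))
  expect_warning(off0 <- align_profiles(flat, flat), "featureless")
  expect_equal(off0, 0)
})

test_that("shrinkage is the percent area loss at matched stations", {
  ph <- phantom_preset("swelling-benchmark", voxel_length = 10)
  fit <- centerline_fit(ph$mask)
  prof <- area_profile(ph$mask, fit)
  s0 <- shrinkage_profile(prof, prof, offset = 0)
  expect_equal(max(abs(s0$shrinkage_pct[!s0$gap])), 0)

  half <- prof
  half$area_mm2 <- prof$area_mm2 / 2
  s50 <- shrinkage_profile(prof, half, offset = 0)
  expect_equal(unique(round(s50$shrinkage_pct[!s50$gap], 9)), 50)

  zero <- prof
  zero$area_mm2[5L] <- NA
  zero$gap[5L] <- TRUE
  sg <- shrinkage_profile(zero, prof, offset = 0)
  expect_true(sg$gap[5L])
})

test_that("segmental shrinkage and a 0.5 mm offset are recovered together", {
  sp <- make_shrinkage_pair()
  fb <- centerline_fit(sp$before$mask)
  fa <- centerline_fit(sp$after$mask)
  pb <- area_profile(sp$before$mask, fb)
  pa <- area_profile(sp$after$mask, fa)
  off <- align_profiles(pb, pa)
  expect_lt(abs(off - sp$offset_mm), 0.05)
  shr <- shrinkage_profile(pb, pa)
  z <- attr(pb, "station_voxel") + 1
  targets <- 100 * (1 - sp$scalings)
  for (i in 1:3) {
    sel <- z >= sp$eval_windows[i, 1L] & z <= sp$eval_windows[i, 2L] &
      !shr$gap
    expect_lt(abs(stats::median(shr$shrinkage_pct[sel]) - targets[i]), 3,
              label = sprintf("segment %d median shrinkage", i))
  }
})
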