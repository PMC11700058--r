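test_that("solid VOI gives BV/TV 1 and BMD equal to the mean density", {
  v <- uniform_volume(520)
  tm <- trabecular_metrics(v, threshold = 300)
  expect_equal(tm$bvtv, 1)
  expect_equal(tm$bmd_mg_cm3, 520)
})

test_that("parallel plates recover thickness and separation from the distance transform", {
  pl <- make_plate_phantom(thickness_vox = 10, gap_vox = 30, voxel_size_um = 18)
  tm <- trabecular_metrics(pl$volume)
  expect_equal(tm$tb_th_um, 180, tolerance = 18 / 180)   # within one voxel
  expect_equal(tm$tb_sp_um, 540, tolerance = 18 / 540)
  expect_equal(tm$tb_n_mm, 1 / ((180 + 540) / 1000), tolerance = 0.05)
})

test_that("random-field phantom BV/TV is recovered within 0.02", {
  ph <- make_trabecular_phantom(shape = 32, target_bvtv = 0.25, seed = 41)
  tm <- trabecular_metrics(ph$volume)
  expect_equal(tm$bvtv, 0.25, tolerance = 0.02 / 0.25)
})

test_that("annulus cortical metrics agree with closed forms", {
  cp <- make_cortical_phantom(outer_radius_mm = 2, inner_radius_mm = 1,
                              voxel_size_um = 20, n_slices = 3)
  cm <- cortical_metrics(cp$volume)
  expect_equal(cm$tt_ar_mm2, 4 * pi, tolerance = 0.02)
  expect_equal(cm$ct_ar_mm2, 3 * pi, tolerance = 0.02)
  expect_equal(cm$ct_th_mm, 1, tolerance = 0.02)
  expect_equal(cm$section_modulus_mm3, pi * 15 / 8, tolerance = 0.02)
  expect_gte(cm$circularity, 0.98)
  # exact partition invariant
  expect_equal(cm$ct_ar_mm2 + cm$ma_ar_mm2, cm$tt_ar_mm2)
})

test_that("ellipse-equivalent axes recover a 2:1 ellipse", {
  el <- make_ellipse_phantom(a_mm = 2, b_mm = 1, voxel_size_um = 20,
                             n_slices = 2)
  cm <- cortical_metrics(el$volume)
  expect_equal(cm$major_axis_mm / cm$minor_axis_mm, 2, tolerance = 0.025)
  expect_equal(cm$major_axis_mm, 4, tolerance = 0.02)
})

test_that("cortical thickness error shrinks with voxel size", {
  # 4x refinement: the one-voxel-scale thickness bias should at least halve
  # (area estimates oscillate in sign with resolution, thickness does not)
  err <- sapply(c(28, 7), function(vs) {
    cp <- make_cortical_phantom(2, 1, voxel_size_um = vs, n_slices = 2)
    abs(cortical_metrics(cp$volume)$ct_th_mm - 1)
  })
  expect_lte(err[2], err[1] * 0.5)
})

test_that("TMD over bone voxels is at least BMD when marrow is less dense", {
  cp <- make_cortical_phantom(2, 1, voxel_size_um = 28, n_slices = 2)
  cm <- cortical_metrics(cp$volume)
  expect_gte(cm$tmd_mg_cm3, mean(cp$volume$values))
  expect_equal(cm$tmd_mg_cm3, 1200, tolerance = 1e-6)
})

test_that("a ring broken in one slice is reported with its slice index", {
  cp <- make_cortical_phantom(2, 1, voxel_size_um = 28, n_slices = 3)
  broken <- cp$volume
  sl <- broken$values[, , 2]
  d <- dim(sl)
  sl[, (d[2] %/% 2):d[2]] <- 100     # cut the ring open in slice 2
  broken$values[, , 2] <- sl
  expect_error(cortical_metrics(broken), "slice 2")
})

test_that("adipose quantification recovers phantom fractions with the shell excluded", {
  ab <- make_abdomen_phantom(0.3, seed = 11, voxel_size_um = 400,
                             n_slices = 8, body_radius_mm = 10)
  ar <- adipose_fraction(ab$volume, ab$standards$air_mean,
                         ab$standards$water_mean)
  expect_equal(ar$percent_adipose, 100 * ab$truth$adipose_fraction,
               tolerance = 1 / 30)
  ab0 <- make_abdomen_phantom(0, seed = 2, voxel_size_um = 400,
                              n_slices = 6, body_radius_mm = 10)
  ar0 <- adipose_fraction(ab0$volume, ab0$standards$air_mean,
                          ab0$standards$water_mean)
  expect_lt(ar0$percent_adipose, 0.5)
  # widening the window into lean HU strictly increases the percentage
  wide <- adipose_fraction(ab$volume, ab$standards$air_mean,
                           ab$standards$water_mean, hu_window = c(-280, 100))
  expect_gt(wide$percent_adipose, ar$percent_adipose)
})

test_that("adipose percentage is invariant to affine rescaling of raw values", {
  ab <- make_abdomen_phantom(0.15, seed = 5, voxel_size_um = 400,
                             n_slices = 6, body_radius_mm = 10)
  r1 <- adipose_fraction(ab$volume, ab$standards$air_mean,
                         ab$standards$water_mean)
  scaled <- density_volume(ab$volume$values * 4 + 70, 400,
                           calibration = list(type = "raw"))
  r2 <- adipose_fraction(scaled, ab$standards$air_mean * 4 + 70,
                         ab$standards$water_mean * 4 + 70)
  expect_equal(r2$percent_adipose, r1$percent_adipose)
})
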