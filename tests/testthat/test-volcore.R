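test_that("two-point HA calibration maps the phantom anchors exactly and is affine", {
  v <- raw_volume(array(c(100, 300, 200, 150), c(4, 1, 1)))
  cal <- calibrate_density(v, low_raw = 100, high_raw = 300)
  expect_equal(cal$values[1, 1, 1], 250)       # low anchor
  expect_equal(cal$values[2, 1, 1], 750)       # high anchor
  expect_equal(cal$values[3, 1, 1], 500)       # midway -> midway
  # round trip through the inverse affine map recovers raw values
  raw_back <- (cal$values - 250) / cal$calibration$slope + 100
  expect_equal(as.numeric(raw_back), as.numeric(v$values), tolerance = 1e-12)
  expect_error(calibrate_density(v, 300, 300), "exceed")
})

test_that("HU calibration anchors air at -1000 and water at 0", {
  v <- raw_volume(array(c(10, 110, 60), c(3, 1, 1)))
  hu <- hu_calibrate(v, air_mean = 10, water_mean = 110)
  expect_equal(hu$values[1, 1, 1], -1000)
  expect_equal(hu$values[2, 1, 1], 0)
  expect_equal(hu$values[3, 1, 1], -500)       # linear interpolation by hand
  expect_error(hu_calibrate(v, 110, 10), "below")
})

test_that("global threshold segmentation respects calibration type", {
  v <- uniform_volume(500)
  expect_true(all(segment_volume(v, 300)$mask))
  expect_false(any(segment_volume(v, 700)$mask))
  raw <- raw_volume(array(1, c(4, 4, 4)))
  expect_error(segment_volume(raw, 300), "HA-calibrated")
  hu <- hu_calibrate(raw_volume(array(60, c(4, 4, 4))), 10, 110)
  expect_error(segment_volume(hu, 300), "HA-calibrated")
})

test_that("segmentation after calibration is invariant to affine raw rescaling", {
  set.seed(1)
  vals <- array(runif(4^3, 0, 1000), c(4, 4, 4))
  m1 <- segment_volume(calibrate_density(raw_volume(vals), 100, 900), 300)$mask
  # rescale raw values and phantom readings consistently
  m2 <- segment_volume(calibrate_density(raw_volume(vals * 3 + 50),
                                         100 * 3 + 50, 900 * 3 + 50), 300)$mask
  expect_identical(m1, m2)
})

test_that("VOI resolution converts mm to slices by round-half-away, half-open", {
  v <- uniform_volume(500, dims = c(4, 4, 300), voxel_size_um = 18)
  # 0.5 mm below the landmark, 2 mm long: 500/18 = 27.8 -> 28; 2000/18 -> 111
  r <- resolve_voi(v, voi_spec(100, 0.5, 2))
  expect_equal(r$start, 128L)
  expect_equal(r$n_slices, 111L)
  expect_equal(dim(r$volume$values)[3], 111L)
  # 0.5 mm window centred 3 mm away at 7 um: 3000/7 -> 429, 500/7 -> 71
  v7 <- uniform_volume(500, dims = c(4, 4, 600), voxel_size_um = 7)
  rc <- resolve_voi(v7, voi_spec(10, 3, 0.5, centred = TRUE))
  expect_equal(rc$n_slices, 71L)
  expect_equal(rc$start, 10L + 429L - 35L)
  # one-slice VOI
  r1 <- resolve_voi(v, voi_spec(100, 0, 18 / 1000))
  expect_equal(r1$n_slices, 1L)
  expect_error(resolve_voi(v, voi_spec(290, 0.5, 2)), "exit")
})

test_that("slab VOI above a landmark selects exactly n sections", {
  v <- uniform_volume(1, dims = c(4, 4, 200))
  r <- slab_voi_above_landmark(v, landmark_slice = 50, n_sections = 100)
  expect_equal(c(r$start, r$stop), c(51L, 151L))
  expect_equal(slab_voi_above_landmark(v, 50, 1)$n_slices, 1L)
  expect_error(slab_voi_above_landmark(v, 150, 100), "exit")
})

test_that("NIfTI volume I/O round-trips values and metadata", {
  set.seed(3)
  v <- density_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), 18,
                      calibration = list(type = "HA"), landmark_slice = 2)
  path <- file.path(tempdir(), "vol_test.nii")
  write_volume(v, path)
  back <- read_volume(path)
  expect_equal(dim(back$values), c(6L, 5L, 4L))
  expect_equal(back$values, v$values, tolerance = 1e-6)  # float32 storage
  expect_equal(back$voxel_size_um, 18)
  expect_equal(back$calibration$type, "HA")
  expect_equal(back$landmark_slice, 2)
})

test_that("rigid transforms invert and serialize consistently", {
  tr <- rigid_transform(c(10, -4, 7), c(30, -12, 5))
  inv <- invert_transform(tr)
  # composing the rotation matrices gives identity
  expect_equal(rotation_matrix <- osteotrack:::rotation_matrix(tr$angles_deg) %*%
                 osteotrack:::rotation_matrix(inv$angles_deg), diag(3),
               tolerance = 1e-10)
  path <- file.path(tempdir(), "tr.json")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$angles_deg, tr$angles_deg)
  expect_equal(back$translation_um, tr$translation_um)
})
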