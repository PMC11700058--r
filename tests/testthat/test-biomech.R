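test_that("stiffness of a pure linear ramp is its slope, offset-invariant", {
  d <- seq(0, 1, length.out = 600)
  cv <- load_curve(d, 500 * d)
  sf <- curve_stiffness(cv)
  expect_equal(sf$stiffness, 500, tolerance = 1e-3)
  # constant load offset does not change the slope
  cv2 <- load_curve(d, 500 * d + 20)
  expect_equal(curve_stiffness(cv2)$stiffness, 500, tolerance = 1e-3)
})

test_that("bilinear curve yields at the plateau load; linear curve is flagged", {
  cv <- make_load_curve(stiffness = 600, yield_load = 120, postyield_slope = 0,
                        ultimate_load = 120, failure_displacement = 0.5,
                        noise_sd = 0, seed = 1)
  sf <- curve_stiffness(cv)
  yp <- yield_point(cv, sf)
  expect_false(yp$flagged)
  expect_equal(yp$yield_load, 120, tolerance = 0.005)
  # crossing sits where the 0.9 S secant meets the plateau: 120 / 540 mm
  expect_equal(yp$d_yield, 120 / 540, tolerance = 0.02)
  # a curve that never softens cannot lose 10% stiffness
  d <- seq(0, 1, length.out = 600)
  lin <- load_curve(d, 700 * d)
  yl <- yield_point(lin, curve_stiffness(lin))
  expect_true(yl$flagged)
  expect_equal(yl$yield_load, max(lin$load))
})

test_that("failure detection, work and post-yield displacement on analytic shapes", {
  # triangle ramp to 100 N at 0.5 mm then abrupt failure: work = 25 N mm
  d <- c(seq(0, 0.5, length.out = 500), 0.5002, 0.5004)
  load <- c(200 * seq(0, 0.5, length.out = 500), 2, 1)
  cv <- load_curve(d, load)
  fw <- failure_and_work(cv, d_yield = 0.5)
  expect_equal(fw$work_to_fracture, 25, tolerance = 0.005)
  expect_equal(fw$d_failure, 0.5002, tolerance = 1e-3)
  # no drop: fracture falls on the last sample
  ramp <- load_curve(seq(0, 1, length.out = 300),
                     seq(0, 150, length.out = 300))
  fw2 <- failure_and_work(ramp, d_yield = 0.4)
  expect_equal(fw2$d_failure, 1)
  expect_equal(fw2$postyield_displacement, 0.6)
})

test_that("work to fracture is invariant under resampling at double rate", {
  cv <- make_load_curve(seed = 5, noise_sd = 0)
  truth <- attr(cv, "truth")
  half <- load_curve(cv$displacement[seq(1, nrow(cv), 2)],
                     cv$load[seq(1, nrow(cv), 2)], sample_rate = 50)
  w1 <- failure_and_work(cv, truth$d_yield)$work_to_fracture
  w2 <- failure_and_work(half, truth$d_yield)$work_to_fracture
  expect_equal(w1, w2, tolerance = 0.005)
})

test_that("beam mechanics: peak moment F L / 4 and tissue strength M / Z", {
  bm <- bending_mechanics(200, span = 15, section_modulus = 3)
  expect_equal(bm$peak_moment, 750)
  expect_equal(bm$tissue_strength, 250)
  # with the annulus phantom's closed-form Z
  bm2 <- bending_mechanics(200, 15, pi * 15 / 8)
  expect_equal(bm2$tissue_strength, 750 / 5.8905, tolerance = 1e-4)
  expect_error(bending_mechanics(-1, 15, 3), "positive")
  expect_error(bending_mechanics(200, 15, 0), "positive")
})

test_that("full analysis recovers generator truth end to end", {
  for (seed in c(3, 17)) {
    cv <- make_load_curve(seed = seed)
    truth <- attr(cv, "truth")
    bd <- bending_analysis(cv, span = 15, section_modulus = 3.0)
    expect_equal(bd$stiffness, truth$stiffness, tolerance = 0.02)
    expect_equal(bd$yield_load, truth$yield_load, tolerance = 0.02)
    expect_equal(bd$ultimate_load, truth$ultimate_load, tolerance = 0.02)
    expect_equal(bd$work_to_fracture, truth$work_to_fracture, tolerance = 0.02)
    expect_equal(bd$tissue_strength, bd$peak_moment / 3.0)
  }
})

test_that("tissue strength scales linearly in load and inversely in Z", {
  grid <- expand.grid(F = c(100, 200, 400), Z = c(2, 4))
  ts <- mapply(function(F, Z) bending_mechanics(F, 15, Z)$tissue_strength,
               grid$F, grid$Z)
  expect_equal(ts, grid$F * 15 / 4 / grid$Z)
})

test_that("curve CSV round trip preserves data and metadata", {
  cv <- make_load_curve(seed = 2)
  path <- file.path(tempdir(), "curve.csv")
  write_load_curve(cv, path, span_mm = 15)
  back <- read_load_curve(path)
  expect_equal(back$displacement, cv$displacement, tolerance = 1e-10)
  expect_equal(back$load, cv$load, tolerance = 1e-10)
  expect_equal(attr(back, "span_mm"), 15)
})
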