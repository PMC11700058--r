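test_that("trabecular phantom hits the target bone fraction and is deterministic", {
  ph <- make_trabecular_phantom(shape = 32, target_bvtv = 0.25, seed = 7)
  frac <- mean(ph$volume$values >= 300)
  expect_gte(frac, 0.23)
  expect_lte(frac, 0.27)
  expect_equal(ph$truth$true_bvtv, frac)
  # degenerate solid
  solid <- make_trabecular_phantom(shape = 32, target_bvtv = 1, seed = 1)
  expect_equal(mean(solid$volume$values >= 300), 1)
  # determinism: same seed twice, bit-identical
  ph2 <- make_trabecular_phantom(shape = 32, target_bvtv = 0.25, seed = 7)
  expect_identical(ph$volume$values, ph2$volume$values)
  expect_error(make_trabecular_phantom(shape = 16), "at least 32")
})

test_that("evolve_phantom realizes the requested remodelling exactly on masks", {
  ph <- make_trabecular_phantom(shape = 32, target_bvtv = 0.3, seed = 2)
  # identity: zero formation and resorption leaves the volume untouched
  ev0 <- evolve_phantom(ph, 0, 0, seed = 1)
  expect_identical(ev0$volume$values, ph$volume$values)
  ev <- evolve_phantom(ph, 0.10, 0.05, seed = 3)
  # truth consistency: independent voxel recount reproduces PhantomTruth
  res <- remodel_fractions(segment_volume(ev$old_volume, 300),
                           segment_volume(ev$volume, 300))
  expect_equal(res$formation_fraction, ev$truth$formation_fraction)
  expect_equal(res$resorption_fraction, ev$truth$resorption_fraction)
  expect_equal(res$n_unique_new, ev$truth$n_added)
  expect_equal(res$n_unique_old, ev$truth$n_removed)
  # requested vs realized within integer rounding
  expect_equal(ev$truth$formation_fraction, 0.10, tolerance = 1e-3)
  expect_equal(ev$truth$resorption_fraction, 0.05, tolerance = 1e-3)
  # swapping roles exchanges formation and resorption
  swapped <- remodel_fractions(segment_volume(ev$volume, 300),
                               segment_volume(ev$old_volume, 300))
  expect_equal(swapped$formation_fraction, res$resorption_fraction)
  expect_equal(swapped$resorption_fraction, res$formation_fraction)
})

test_that("formation is surface accretion: no new disconnected bone", {
  ph <- make_trabecular_phantom(shape = 32, target_bvtv = 0.3, seed = 5)
  ev <- evolve_phantom(ph, 0.15, 0.0, seed = 6)
  old_mask <- ph$volume$values >= 300
  new_mask <- ev$volume$values >= 300
  added <- new_mask & !old_mask
  # every added voxel must touch the rest of the new structure
  lab <- osteotrack:::label_components(new_mask)
  n_before <- max(osteotrack:::label_components(old_mask))
  expect_lte(max(lab), n_before)  # accretion cannot create new components
})

test_that("cortical annulus phantom records closed-form geometry", {
  cp <- make_cortical_phantom(outer_radius_mm = 2, inner_radius_mm = 1,
                              voxel_size_um = 20, n_slices = 2)
  expect_equal(cp$truth$ct_ar_mm2, 3 * pi)
  expect_equal(cp$truth$tt_ar_mm2, 4 * pi)
  expect_equal(cp$truth$section_modulus_mm3, pi * 15 / 8)
  # voxel-counted areas near analytic values
  ring <- cp$volume$values[, , 1] >= 700
  a_vox <- sum(ring) * (0.02)^2
  expect_equal(a_vox, 3 * pi, tolerance = 0.01)
  # solid rod degenerate
  rod <- make_cortical_phantom(outer_radius_mm = 1, inner_radius_mm = 0,
                               voxel_size_um = 20, n_slices = 2)
  expect_equal(rod$truth$ma_ar_mm2, 0)
  expect_error(make_cortical_phantom(2, 1, voxel_size_um = 500), "3 voxels")
})

test_that("abdomen phantom: exact cavity fraction, shell in window but outside cavity", {
  ab <- make_abdomen_phantom(adipose_fraction = 0.3, seed = 11,
                             voxel_size_um = 400, n_slices = 8,
                             body_radius_mm = 10)
  expect_equal(ab$truth$adipose_fraction, 0.3, tolerance = 2e-3)
  hu <- hu_calibrate(ab$volume, ab$standards$air_mean, ab$standards$water_mean)
  # standards measured from the phantom land near their nominal raw values
  expect_equal(ab$standards$air_mean, 10, tolerance = 1)
  expect_equal(ab$standards$water_mean, 110, tolerance = 1)
  # subcutaneous shell voxels fall inside the adipose HU window
  d <- dim(hu$values)
  ctr <- (d[1] + 1) / 2
  rb <- 10 / 0.4
  shell_vox <- hu$values[round(ctr + rb - 1), round(ctr), 4]
  expect_gte(shell_vox, -280)
  expect_lte(shell_vox, -150)
  # zero-fraction phantom has no cavity voxels in the window
  ab0 <- make_abdomen_phantom(0, seed = 1, voxel_size_um = 400, n_slices = 4,
                              body_radius_mm = 10)
  expect_equal(ab0$truth$adipose_fraction, 0)
})

test_that("synthetic Raman spectra follow their construction", {
  # all-zero construction gives a flat zero spectrum
  z <- make_raman_spectrum(band_amplitudes = c(`960` = 0), pmma_scale = 0,
                           noise_sd = 0, seed = 1)
  expect_equal(max(abs(z$intensity)), 0)
  # two-band construction: downstream MMR equals the height ratio
  s <- make_raman_spectrum(band_amplitudes = c(`960` = 8, `1668` = 1),
                           pmma_scale = 0.2, noise_sd = 0, seed = 1)
  expect_equal(attr(s, "truth")$mmr, 8)
  # determinism
  s2 <- make_raman_spectrum(seed = 42)
  s3 <- make_raman_spectrum(seed = 42)
  expect_identical(s2$intensity, s3$intensity)
  expect_error(make_raman_spectrum(band_amplitudes = c(`500` = 1)),
               "outside the wavenumber grid")
})

test_that("synthetic load curves record analytic truth", {
  # plateau case: analytic yield equals the plateau load
  cv <- make_load_curve(stiffness = 600, yield_load = 120, postyield_slope = 0,
                        ultimate_load = 120, failure_displacement = 0.5,
                        noise_sd = 0, seed = 1)
  expect_equal(attr(cv, "truth")$yield_load, 120)
  # triangle ramp: work is the triangle area
  tri <- make_load_curve(stiffness = 200, yield_load = 100, postyield_slope = 0,
                         ultimate_load = 100, failure_displacement = 0.5,
                         noise_sd = 0, seed = 1)
  expect_equal(attr(tri, "truth")$work_to_fracture, 0.5 * 100 * 0.5)
  # determinism and invalid parameter combinations
  a <- make_load_curve(seed = 9)
  b <- make_load_curve(seed = 9)
  expect_identical(a$load, b$load)
  expect_error(make_load_curve(yield_load = 300, ultimate_load = 200),
               "not exceed")
  expect_error(make_load_curve(postyield_slope = 800), "below")
  expect_error(make_load_curve(yield_load = 150, ultimate_load = 211,
                               postyield_slope = 0), "inconsistent")
})
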