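test_that("despike removes cosmic rays and leaves clean channels untouched", {
  s <- make_raman_spectrum(spike_positions = c(1100), spike_height = 800,
                           seed = 8)
  clean <- make_raman_spectrum(seed = 8)      # same noise, no spike
  ds <- despike(s)
  noise_sd <- attr(s, "truth")$noise_sd
  expect_lt(max(abs(ds$intensity - clean$intensity)), 3 * noise_sd)
  # spike-free spectrum passes through unchanged
  expect_identical(despike(clean)$intensity, clean$intensity)
  # two adjacent spikes are both replaced
  s2 <- make_raman_spectrum(spike_positions = c(1100, 1101),
                            spike_height = 800, seed = 8)
  ds2 <- despike(s2)
  expect_lt(max(abs(ds2$intensity - clean$intensity)), 3 * noise_sd)
  # a spectrum that is mostly spikes is rejected
  set.seed(1)
  junk <- raman_spectrum(800:1000, rnorm(201) + 500 * (800:1000 %% 3 == 0))
  expect_error(despike(junk), "unusable")
  expect_error(despike(raman_spectrum(1:10, rnorm(10))), "16 channels")
})

test_that("polynomial baseline is removed without touching band heights", {
  # pure linear background, no bands: residual is flat zero
  w <- seq(800, 1800, 1)
  lin <- raman_spectrum(w, 2 + 0.004 * (w - 800))
  out <- baseline_subtract(lin, poly_order = 1)
  expect_lt(max(abs(out$intensity)), 1e-8)
  # Gaussian band on a cubic background: band height recovered within 2%
  s <- make_raman_spectrum(band_amplitudes = c(`960` = 10),
                           baseline_coeffs = c(1, 2, -1, 0.5),
                           pmma_scale = 0, noise_sd = 0, seed = 1)
  bs <- baseline_subtract(s)
  expect_equal(band_height(bs, 960), 10, tolerance = 0.02)
  # idempotence: a second pass changes nearly nothing
  bs2 <- baseline_subtract(bs)
  expect_lt(max(abs(bs2$intensity - bs$intensity)) / max(bs$intensity), 0.005)
  expect_error(baseline_subtract(raman_spectrum(1:40, rnorm(40)),
                                 poly_order = 10), "too high")
})

test_that("band heights read construction values and handle edge windows", {
  s <- make_raman_spectrum(band_amplitudes = c(`960` = 8), pmma_scale = 0,
                           noise_sd = 0, seed = 1)
  expect_equal(band_height(s, 960), 8, tolerance = 1e-3)
  z <- make_raman_spectrum(band_amplitudes = c(`960` = 0), pmma_scale = 0,
                           noise_sd = 0, seed = 1)
  expect_equal(band_height(z, 1200), 0)
  expect_error(band_height(s, 805), "outside the grid")
})

test_that("resin subtraction finds the mixing scale and zeroes the 812 peak", {
  ref <- pmma_reference()
  bone <- make_raman_spectrum(pmma_scale = 0, noise_sd = 0, seed = 1)
  mixed <- raman_spectrum(bone$wavenumber, bone$intensity + 0.4 * ref$intensity)
  out <- pmma_subtract(mixed, ref)
  expect_equal(attr(out, "alpha"), 0.4, tolerance = 0.01)
  expect_lt(band_height(out, 812) / band_height(out, 960), 5e-3)
  # no resin: scale near zero, spectrum essentially unchanged
  out0 <- pmma_subtract(bone, ref)
  expect_lt(attr(out0, "alpha"), 0.01)
  # negative scale clamps to zero with a warning
  neg <- raman_spectrum(bone$wavenumber, bone$intensity - 0.2 * ref$intensity)
  expect_warning(outn <- pmma_subtract(neg, ref), "clamped")
  expect_equal(attr(outn, "alpha"), 0)
})

test_that("v1PO4 FWHM interpolates half-maximum crossings", {
  # sigma = 4 : FWHM = 2 sqrt(2 ln 2) * 4 = 9.42, crystallinity 0.1062
  s <- make_raman_spectrum(band_amplitudes = c(`960` = 10),
                           band_fwhm = c(`960` = 2 * sqrt(2 * log(2)) * 4),
                           pmma_scale = 0, noise_sd = 0, seed = 1)
  fw <- v1po4_fwhm(s)
  expect_equal(fw, 9.4195, tolerance = 0.005)
  expect_equal(1 / fw, 0.1062, tolerance = 0.005)
  # doubling sigma halves crystallinity
  s2 <- make_raman_spectrum(band_amplitudes = c(`960` = 10),
                            band_fwhm = c(`960` = 2 * sqrt(2 * log(2)) * 8),
                            pmma_scale = 0, noise_sd = 0, seed = 1)
  expect_equal(v1po4_fwhm(s2) / fw, 2, tolerance = 0.02)
  # grid refinement changes the estimate by < 2%
  s_half <- make_raman_spectrum(band_amplitudes = c(`960` = 10),
                                band_fwhm = c(`960` = 9.42), pmma_scale = 0,
                                noise_sd = 0, seed = 1,
                                wavenumbers = seq(800, 1800, 0.5))
  s_full <- make_raman_spectrum(band_amplitudes = c(`960` = 10),
                                band_fwhm = c(`960` = 9.42), pmma_scale = 0,
                                noise_sd = 0, seed = 1)
  expect_equal(v1po4_fwhm(s_half), v1po4_fwhm(s_full), tolerance = 0.02)
})

test_that("compute_params reproduces construction ratios and scale invariance", {
  ref <- pmma_reference()
  s <- make_raman_spectrum(band_amplitudes = c(`960` = 8, `1668` = 1,
                                               `1070` = 1.3),
                           pmma_scale = 0.2, noise_sd = 0, seed = 1)
  p <- compute_params(s, ref)
  expect_equal(p$mmr, 8, tolerance = 0.01)
  expect_equal(p$carb_phos, 0.1625, tolerance = 0.01)
  # global intensity scaling leaves every ratio unchanged (full band set,
  # so all seven ratios are well defined)
  sf <- make_raman_spectrum(pmma_scale = 0.25, noise_sd = 0, seed = 1)
  pf <- compute_params(sf, ref)
  s5 <- raman_spectrum(sf$wavenumber, sf$intensity * 5)
  p5 <- compute_params(s5, ref)
  for (nm in c("mmr", "carb_phos", "nanoporosity", "crystallinity",
               "hyp_pro", "gag_amideIII", "collagen_maturity"))
    expect_equal(p5[[nm]], pf[[nm]], tolerance = 1e-8)
  # no resin: nanoporosity vanishes
  s0 <- make_raman_spectrum(pmma_scale = 0, noise_sd = 0, seed = 1)
  expect_lt(compute_params(s0, ref)$nanoporosity, 5e-3)
})

test_that("nanoporosity must be computed before resin subtraction", {
  ref <- pmma_reference()
  s <- make_raman_spectrum(pmma_scale = 0.3, noise_sd = 0, seed = 1)
  p <- compute_params(s, ref)
  # swapping the order (post-subtraction 812/960) gives a detectably
  # different, near-zero value
  sub <- pmma_subtract(s, ref)
  nano_post <- band_height(sub, 812) / band_height(sub, 960)
  expect_gt(p$nanoporosity, 10 * max(nano_post, 1e-6))
  expect_equal(p$nanoporosity, attr(s, "truth")$nanoporosity,
               tolerance = 0.02)
})

test_that("line-scan distribution summary matches sampling theory and hand histograms", {
  set.seed(6)
  ds <- linescan_summary(rnorm(500, 11, 1))
  expect_equal(ds$mean, 11, tolerance = 0.15 / 11)
  expect_equal(ds$fwhm, 2 * sqrt(2 * log(2)), tolerance = 0.3 / 2.355)
  expect_gt(ds$r2_gaussian, 0.95)
  expect_true(ds$normal)
  # weighted mean equals the arithmetic mean within half a bin width
  x <- rnorm(300, 5, 0.7)
  ds2 <- linescan_summary(x)
  half_bin <- diff(ds2$bin_edges)[1] / 2
  expect_lt(abs(ds2$mean - mean(x)), half_bin)
  # hand histogram {1: 20%, 2: 60%, 3: 20%}: weighted mean exactly 2
  vals <- c(rep(1, 20), rep(2, 60), rep(3, 20))
  ds3 <- linescan_summary(vals, n_bins = 3)
  expect_equal(ds3$mean, 2)
  # degenerate input
  expect_error(linescan_summary(rep(2, 100)), "identical")
  expect_error(linescan_summary(rnorm(10)), "at least 20")
})

test_that("line-scan pipeline excludes non-bone points by the MMR floor", {
  ref <- pmma_reference()
  bone <- lapply(1:3, function(i) make_raman_spectrum(seed = i))
  resin <- lapply(4:5, function(i)
    make_raman_spectrum(band_amplitudes = c(`960` = 0.1, `1668` = 1),
                        pmma_scale = 1, seed = i))
  tab <- linescan_params(c(bone, resin), ref, mmr_floor = 1)
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "n_excluded"), 2L)
})

test_that("spectrum CSV round trip preserves the series", {
  s <- make_raman_spectrum(seed = 3)
  path <- file.path(tempdir(), "spec.csv")
  write_spectrum(s, path)
  back <- read_spectrum(path)
  expect_equal(back$wavenumber, s$wavenumber)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-12)
})
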