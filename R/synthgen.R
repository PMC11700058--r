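# Synthetic phantom, spectrum and load-curve generators. Each generator is a
# pure function of its arguments including `seed`, and records the realized
# ground truth alongside the object so downstream recovery can be checked
# exactly.

#' Trabecular bone phantom from a thresholded Gaussian random field
#'
#' A Gaussian white-noise field is smoothed at a configurable correlation
#' length and thresholded at the quantile that hits the requested bone
#' volume fraction, producing connected plate/rod-like structures. Densities
#' are an anti-aliased ramp across the threshold surface: bone voxels lie
#' above the 300 mg/cm3 trabecular cutoff, background below it, and the
#' transition is smooth so that resampling plus re-thresholding reconstructs
#' the surface at sub-voxel accuracy (emulating partial-volume behaviour).
#'
#' @param shape volume dimensions, a single integer (cube) or length-3
#'   vector; each dimension must be >= 32.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param target_bvtv target bone volume fraction in (0, 1].
#' @param seed integer seed.
#' @param corr_length smoothing correlation length in voxels.
#' @return List with `volume` (HA-calibrated `density_volume`) and `truth`
#'   (realized `true_bvtv`, `threshold`, `seed`).
#' @export
make_trabecular_phantom <- function(shape = 48, voxel_size_um = 18,
                                    target_bvtv = 0.25, seed = 1,
                                    corr_length = 5) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (any(shape < 32L)) stopf("phantom shape must be at least 32 per side")
  if (target_bvtv <= 0 || target_bvtv > 1)
    stopf("`target_bvtv` must be in (0, 1]")
  with_seed(seed, {
    f <- array(rnorm(prod(shape)), shape)
    f <- gauss_smooth3(f, corr_length)
    f <- (f - mean(f)) / sd(f)
    # threshold at the exact empirical quantile -> realized BV/TV hits target
    thr <- if (target_bvtv >= 1) -Inf else
      quantile(f, probs = 1 - target_bvtv, names = FALSE, type = 1)
    bone <- f >= thr
    realized <- mean(bone)
    if (abs(realized - target_bvtv) > 0.02)
      stopf("could not reach target BV/TV %.3f (realized %.3f)",
            target_bvtv, realized)
    # anti-aliased density ramp: 300 at the iso-surface, bone above, bg below
    grad <- sd(f) / corr_length            # typical field change per voxel
    dens <- 300 + 450 * tanh((f - thr) / (3 * grad))
    vol <- density_volume(dens, voxel_size_um,
                          calibration = list(type = "HA"))
    list(volume = vol,
         truth = list(true_bvtv = realized, threshold = 300, seed = seed))
  })
}

#' Parallel-plate phantom with known thickness and separation
#'
#' Plates normal to the scan axis, padded by half-gaps at both stack ends
#' so every plate is interior (the open volume boundary acts as a mirror
#' for the gaps). Used as a closed-form oracle for local-thickness
#' morphometry.
#'
#' @param thickness_vox plate thickness in voxels.
#' @param gap_vox gap between plates in voxels.
#' @param n_plates number of plates.
#' @param lateral_vox in-plane extent in voxels.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @return List with `volume` (HA-calibrated) and `truth` (`tb_th_um`,
#'   `tb_sp_um`, `true_bvtv`).
#' @export
make_plate_phantom <- function(thickness_vox = 10, gap_vox = 30,
                               n_plates = 3, lateral_vox = 48,
                               voxel_size_um = 18) {
  halfgap <- gap_vox %/% 2L
  nz <- 2L * halfgap + n_plates * thickness_vox + (n_plates - 1L) * gap_vox
  z <- seq_len(nz)
  in_plate <- rep(FALSE, nz)
  for (p in seq_len(n_plates)) {
    s <- halfgap + (p - 1L) * (thickness_vox + gap_vox) + 1L
    in_plate[s:(s + thickness_vox - 1L)] <- TRUE
  }
  bone <- array(rep(in_plate, each = lateral_vox^2),
                c(lateral_vox, lateral_vox, nz))
  dens <- ifelse(bone, 750, 100)
  vol <- density_volume(dens, voxel_size_um, calibration = list(type = "HA"))
  list(volume = vol,
       truth = list(tb_th_um = thickness_vox * voxel_size_um,
                    tb_sp_um = gap_vox * voxel_size_um,
                    true_bvtv = mean(bone)))
}

#' Evolve a phantom into a second timepoint with known remodelling
#'
#' Builds the later timepoint by surface accretion (formation) and surface
#' removal (resorption). Voxel counts are chosen so that, relative to the
#' union of the two bone sets, unique-new / union equals
#' `formation_fraction` and unique-old / union equals `resorption_fraction`
#' up to integer rounding; the exactly realized fractions are recorded.
#' Remodelling is applied in spatially clustered patches (a smoothed random
#' field ranks the surface candidates), mimicking remodelling packets and
#' keeping all new bone connected to the existing surface.
#'
#' @param phantom result of [make_trabecular_phantom()] (or a list with a
#'   `volume` entry).
#' @param formation_fraction,resorption_fraction requested fractions in
#'   `[0, 1)` with sum < 1.
#' @param seed integer seed.
#' @param threshold bone density cutoff (mg/cm3) defining the structure.
#' @return List with `volume` (the new timepoint), `truth`
#'   (`formation_fraction`, `resorption_fraction` realized exactly,
#'   `n_added`, `n_removed`, `n_union`), and `old_volume`.
#' @export
evolve_phantom <- function(phantom, formation_fraction = 0.10,
                           resorption_fraction = 0.05, seed = 1,
                           threshold = 300) {
  vol <- if (inherits(phantom, "density_volume")) phantom else phantom$volume
  f <- formation_fraction
  r <- resorption_fraction
  if (f < 0 || r < 0 || f >= 1 || f + r > 1)
    stopf("fractions must be >= 0 with formation < 1 and sum <= 1")
  bone0 <- vol$values >= threshold
  B <- sum(bone0)
  n_add <- as.integer(round(f * B / (1 - f)))
  n_rem <- as.integer(round(r * (B + n_add)))
  # remodelling packets are a few voxels deep (apposition/erosion depth),
  # so voxels are taken in `n_layers` ranked layers rather than one sheet;
  # densities follow the same anti-aliased depth ramp as the base phantom
  # (300 mg/cm3 at the surface) so that partial-volume behaviour stays
  # consistent under resampling
  n_layers <- 3L
  ramp <- function(layer) 300 + 450 * tanh(layer / 3)
  with_seed(seed, {
    w <- gauss_smooth3(array(rnorm(length(bone0)), dim(bone0)), 3)
    new_bone <- bone0
    dens <- vol$values
    removed <- integer(0)
    quota_rem <- max(1L, ceiling(n_rem / n_layers))
    L_rem <- if (n_rem > 0) ceiling(n_rem / quota_rem) else 1L
    layer <- 0L
    # resorption: strip ranked surface bone voxels, layer by layer; the
    # cavity mouth (first layer) ends deepest below threshold, the cavity
    # floor just below it
    while (length(removed) < n_rem) {
      layer <- layer + 1L
      surf <- which(new_bone & (edt(new_bone) <= 1))
      if (length(surf) == 0L) stopf("insufficient surface voxels for resorption")
      take <- min(n_rem - length(removed), quota_rem, length(surf))
      sel <- surf[order(w[surf], decreasing = TRUE)][seq_len(take)]
      new_bone[sel] <- FALSE
      dens[sel] <- 600 - ramp(max(1L, L_rem - layer + 1L))
      removed <- c(removed, sel)
    }
    # formation: accrete ranked background voxels adjacent to remaining
    # bone; density decreases towards the new surface so the packet stays
    # anti-aliased like the base structure
    added <- integer(0)
    forbidden <- removed   # never re-add a resorbed voxel
    quota_add <- max(1L, ceiling(n_add / n_layers))
    L_add <- if (n_add > 0) ceiling(n_add / quota_add) else 1L
    layer <- 0L
    while (length(added) < n_add) {
      layer <- layer + 1L
      cand <- which(!new_bone & (edt(!new_bone) <= 1))
      cand <- setdiff(cand, forbidden)
      if (length(cand) == 0L) stopf("insufficient surface voxels for formation")
      take <- min(n_add - length(added), quota_add, length(cand))
      sel <- cand[order(w[cand], decreasing = TRUE)][seq_len(take)]
      new_bone[sel] <- TRUE
      dens[sel] <- ramp(max(1L, L_add - layer + 1L))
      added <- c(added, sel)
    }
    n_union <- B + length(added)
    newvol <- density_volume(dens, vol$voxel_size_um, vol$calibration)
    list(volume = newvol, old_volume = vol,
         truth = list(formation_fraction = length(added) / n_union,
                      resorption_fraction = length(removed) / n_union,
                      n_added = length(added), n_removed = length(removed),
                      n_union = n_union, seed = seed))
  })
}

#' Cortical annulus phantom with closed-form geometry
#'
#' Circular annulus cross-section extruded along the scan axis, with
#' analytic total, cortical and marrow areas, thickness and section modulus
#' recorded for oracle tests.
#'
#' @param outer_radius_mm,inner_radius_mm periosteal and endosteal radii
#'   (`inner < outer`; `inner = 0` gives a solid rod).
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param n_slices number of identical slices to extrude.
#' @param density cortical density in mg/cm3.
#' @param margin_vox background margin around the annulus, in voxels.
#' @return List with `volume` (HA-calibrated) and `truth` (`tt_ar_mm2`,
#'   `ct_ar_mm2`, `ma_ar_mm2`, `ct_th_mm`, `section_modulus_mm3`).
#' @export
make_cortical_phantom <- function(outer_radius_mm = 2, inner_radius_mm = 1,
                                  voxel_size_um = 7, n_slices = 8,
                                  density = 1200, margin_vox = 6) {
  ro <- outer_radius_mm; ri <- inner_radius_mm
  if (ri >= ro) stopf("`inner_radius_mm` must be below `outer_radius_mm`")
  vox_mm <- voxel_size_um / 1000
  if (ro / vox_mm < 3 || (ri > 0 && ri / vox_mm < 3))
    stopf("radii must span at least 3 voxels at this voxel size")
  n <- 2L * (as.integer(ceiling(ro / vox_mm)) + as.integer(margin_vox))
  ctr <- (n + 1) / 2
  xy <- (seq_len(n) - ctr) * vox_mm
  r2 <- outer(xy^2, xy^2, `+`)
  ring <- r2 <= ro^2 & r2 >= ri^2
  sl <- ifelse(ring, density, 100)
  vol <- density_volume(array(rep(sl, n_slices), c(n, n, n_slices)),
                        voxel_size_um, calibration = list(type = "HA"))
  list(volume = vol,
       truth = list(tt_ar_mm2 = pi * ro^2,
                    ct_ar_mm2 = pi * (ro^2 - ri^2),
                    ma_ar_mm2 = pi * ri^2,
                    ct_th_mm = ro - ri,
                    section_modulus_mm3 = pi * (ro^4 - ri^4) / (4 * ro)))
}

#' Elliptical cortical phantom (for axis-ratio oracles)
#'
#' Solid ellipse cross-section with semi-axes `a_mm` (x) and `b_mm` (y).
#'
#' @param a_mm,b_mm semi-axes in millimetres.
#' @param voxel_size_um isotropic voxel size.
#' @param n_slices slices to extrude.
#' @return List with `volume` and `truth` (`major_axis_mm`, `minor_axis_mm`).
#' @export
make_ellipse_phantom <- function(a_mm = 2, b_mm = 1, voxel_size_um = 7,
                                 n_slices = 4) {
  vox_mm <- voxel_size_um / 1000
  n <- 2L * (as.integer(ceiling(max(a_mm, b_mm) / vox_mm)) + 6L)
  ctr <- (n + 1) / 2
  xy <- (seq_len(n) - ctr) * vox_mm
  inside <- outer(xy^2 / a_mm^2, xy^2 / b_mm^2, `+`) <= 1
  sl <- ifelse(inside, 1200, 100)
  vol <- density_volume(array(rep(sl, n_slices), c(n, n, n_slices)),
                        voxel_size_um, calibration = list(type = "HA"))
  list(volume = vol,
       truth = list(major_axis_mm = 2 * max(a_mm, b_mm),
                    minor_axis_mm = 2 * min(a_mm, b_mm)))
}

#' Abdomen phantom with air/water standards and known adipose fraction
#'
#' Concentric cylinder in raw (uncalibrated) grey values: air background, a
#' subcutaneous-fat shell whose values fall inside the adipose HU window, an
#' inner cavity of lean tissue with clustered adipose blobs at a known voxel
#' fraction, plus separate air and water standard patches. Raw grey values
#' follow `HU = 10 * (raw - 110)`: air 10 (-1000 HU), water 110 (0 HU),
#' adipose 90 (-200 HU), lean 114 (+40 HU), so the calibration arithmetic is
#' hand-checkable. The cavity adipose fraction equals `adipose_fraction`
#' exactly by construction (quantile threshold on a smoothed field).
#'
#' @param adipose_fraction target cavity adipose voxel fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param body_radius_mm outer body radius.
#' @param shell_mm subcutaneous shell thickness (must be below the analysis
#'   erosion depth, default pipeline value 1 mm).
#' @param voxel_size_um voxel size in micrometres.
#' @param n_slices number of slices.
#' @param noise_sd raw-value Gaussian noise (1 raw unit = 10 HU).
#' @return List with `volume` (raw), `truth` (`adipose_fraction` realized,
#'   `air_mean`, `water_mean`, patch index lists), and `standards`
#'   (measured air/water patch means).
#' @export
make_abdomen_phantom <- function(adipose_fraction = 0.30, seed = 1,
                                 body_radius_mm = 12, shell_mm = 0.8,
                                 voxel_size_um = 200, n_slices = 20,
                                 noise_sd = 1) {
  if (adipose_fraction < 0 || adipose_fraction > 1)
    stopf("`adipose_fraction` must be in [0, 1]")
  vox_mm <- voxel_size_um / 1000
  rb <- body_radius_mm / vox_mm
  rc <- (body_radius_mm - shell_mm) / vox_mm
  n <- 2L * as.integer(ceiling(rb) + 12L)
  ctr <- (n + 1) / 2
  xy <- seq_len(n) - ctr
  r2 <- outer(xy^2, xy^2, `+`)
  body2d <- r2 <= rb^2
  cavity2d <- r2 <= rc^2
  with_seed(seed, {
    raw <- array(10, c(n, n, n_slices))                   # air
    shell <- body2d & !cavity2d
    for (k in seq_len(n_slices)) {
      sl <- raw[, , k]
      sl[shell] <- 90                                     # subcutaneous fat
      sl[cavity2d] <- 114                                 # lean
      raw[, , k] <- sl
    }
    cav3d <- array(cavity2d, c(n, n, n_slices))
    if (adipose_fraction > 0) {
      fld <- gauss_smooth3(array(rnorm(n * n * n_slices), c(n, n, n_slices)), 3)
      cv <- fld[cav3d]
      thr <- quantile(cv, probs = 1 - adipose_fraction, names = FALSE, type = 1)
      adipose <- cav3d & fld >= thr
      raw[adipose] <- 90
      realized <- sum(adipose) / sum(cav3d)
    } else {
      adipose <- array(FALSE, dim(raw))
      realized <- 0
    }
    # standard patches in one corner, clear of the body
    patch <- function(x0, y0, w = 6L) {
      ix <- x0 + seq_len(w); iy <- y0 + seq_len(w)
      as.matrix(expand.grid(x = ix, y = iy))
    }
    airp <- patch(1L, 1L)
    watp <- patch(1L, 10L)
    for (k in seq_len(n_slices)) {
      sl <- raw[, , k]
      sl[airp] <- 10
      sl[watp] <- 110
      raw[, , k] <- sl
    }
    raw <- raw + array(rnorm(length(raw), 0, noise_sd), dim(raw))
    vol <- density_volume(raw, voxel_size_um, calibration = list(type = "raw"))
    air_mean <- mean(vapply(seq_len(n_slices),
                            function(k) mean(raw[, , k][airp]), 0))
    water_mean <- mean(vapply(seq_len(n_slices),
                              function(k) mean(raw[, , k][watp]), 0))
    list(volume = vol,
         truth = list(adipose_fraction = realized, seed = seed,
                      shell_mm = shell_mm, body_radius_mm = body_radius_mm),
         standards = list(air_mean = air_mean, water_mean = water_mean))
  })
}

# deterministic pMMA embedding-resin reference: dominated by its ~812 cm-1
# peak, minor CH/C=O bands elsewhere.
#' Synthetic pMMA reference spectrum
#'
#' Deterministic stand-in for an embedding-resin (polymethylmethacrylate)
#' reference spectrum, dominated by the ~812 cm-1 peak. Labelled synthetic:
#' it is generated, not measured.
#'
#' @param wavenumbers grid in cm-1 (default 800..1800 step 1).
#' @return A `raman_spectrum`.
#' @export
pmma_reference <- function(wavenumbers = seq(800, 1800, by = 1)) {
  peaks <- list(c(812, 10, 10), c(1450, 2, 16), c(1730, 1.2, 16))
  y <- rep(0, length(wavenumbers))
  for (p in peaks) {
    sg <- p[3] / (2 * sqrt(2 * log(2)))
    y <- y + p[2] * exp(-(wavenumbers - p[1])^2 / (2 * sg^2))
  }
  raman_spectrum(wavenumbers, y)
}

#' Synthetic bone Raman spectrum with known band construction
#'
#' Sum of Gaussian bands at named centres, a polynomial background, a scaled
#' pMMA resin component, optional cosmic-ray spikes, and Gaussian noise.
#' The construction band ratios (the downstream compositional parameters)
#' are recorded as ground truth.
#'
#' @param band_amplitudes named numeric vector, centre (cm-1) -> peak height.
#' @param band_fwhm named numeric vector, centre -> FWHM in cm-1; centres
#'   missing from it get `default_fwhm`.
#' @param baseline_coeffs polynomial background coefficients (intercept
#'   first), evaluated on a unit-scaled wavenumber axis.
#' @param pmma_scale multiplier on the [pmma_reference()] component.
#' @param spike_positions wavenumbers receiving cosmic-ray spikes.
#' @param spike_height spike amplitude.
#' @param noise_sd Gaussian noise SD; default 0.5% of the largest band.
#' @param seed integer seed (noise only).
#' @param wavenumbers grid in cm-1, step <= 1, spanning 800-1800.
#' @param default_fwhm fallback FWHM in cm-1.
#' @return A `raman_spectrum` with attribute `truth`: the construction
#'   parameter values (`mmr`, `carb_phos`, `nanoporosity`, `crystallinity`,
#'   `hyp_pro`, `gag_amideIII`, `collagen_maturity`) implied by the bands.
#' @export
make_raman_spectrum <- function(band_amplitudes = c(`960` = 11, `1070` = 1.98,
                                                    `1245` = 0.8, `1375` = 0.36,
                                                    `854` = 0.9, `872` = 0.68,
                                                    `1670` = 1.0, `1690` = 0.37),
                                band_fwhm = c(`960` = 9.42, `1668` = 10,
                                              `1670` = 10, `1690` = 10),
                                baseline_coeffs = c(0, 0, 0, 0),
                                pmma_scale = 0.25,
                                spike_positions = numeric(0),
                                spike_height = 100,
                                noise_sd = NULL,
                                seed = 1,
                                wavenumbers = seq(800, 1800, by = 1),
                                default_fwhm = 12) {
  if (any(diff(wavenumbers) <= 0) || any(diff(wavenumbers) > 1 + 1e-9))
    stopf("`wavenumbers` must be ascending with step <= 1")
  centers <- as.numeric(names(band_amplitudes))
  if (any(is.na(centers)))
    stopf("`band_amplitudes` must be named by band centre")
  if (any(centers < min(wavenumbers) | centers > max(wavenumbers)))
    stopf("band centre outside the wavenumber grid")
  y <- rep(0, length(wavenumbers))
  for (i in seq_along(centers)) {
    fw <- band_fwhm[as.character(centers[i])]
    if (is.na(fw)) fw <- default_fwhm
    sg <- fw / (2 * sqrt(2 * log(2)))
    y <- y + band_amplitudes[i] *
      exp(-(wavenumbers - centers[i])^2 / (2 * sg^2))
  }
  ref <- pmma_reference(wavenumbers)
  y <- y + pmma_scale * ref$intensity
  u <- (wavenumbers - 800) / 1000
  base <- rep(0, length(u))
  for (j in seq_along(baseline_coeffs))
    base <- base + baseline_coeffs[j] * u^(j - 1)
  y <- y + base
  for (sp in spike_positions) {
    i <- which.min(abs(wavenumbers - sp))
    y[i] <- y[i] + spike_height
  }
  amp_max <- if (length(band_amplitudes)) max(band_amplitudes) else 1
  if (is.null(noise_sd)) noise_sd <- 0.005 * amp_max
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(length(y), 0, noise_sd))
  h <- function(cn) {
    v <- band_amplitudes[as.character(cn)]
    if (is.na(v)) 0 else unname(v)
  }
  amide1 <- max(h(1668), h(1670))   # Amide I envelope height
  fw960 <- band_fwhm["960"]
  if (is.na(fw960)) fw960 <- default_fwhm
  ref812 <- max(ref$intensity[abs(wavenumbers - 812) <= 10])
  truth <- list(
    mmr = if (amide1 > 0) h(960) / amide1 else NA_real_,
    carb_phos = if (h(960) > 0) h(1070) / h(960) else NA_real_,
    nanoporosity = if (h(960) > 0) pmma_scale * ref812 / h(960) else NA_real_,
    crystallinity = 1 / fw960,
    hyp_pro = if (h(854) > 0) h(872) / h(854) else NA_real_,
    gag_amideIII = if (h(1245) > 0) h(1375) / h(1245) else NA_real_,
    collagen_maturity = if (h(1690) > 0) h(1670) / h(1690) else NA_real_,
    pmma_scale = pmma_scale, noise_sd = noise_sd, seed = seed)
  s <- raman_spectrum(wavenumbers, as.numeric(y))
  attr(s, "truth") <- truth
  s
}

#' Synthetic three-point-bending load-displacement curve
#'
#' Piecewise curve: linear loading at `stiffness` to the yield point
#' (`yield_load`), linear hardening at `postyield_slope` to `ultimate_load`,
#' a flat plateau to `failure_displacement`, then an abrupt failure drop.
#' Sampled at `sample_rate` for a crosshead speed `speed_mm_min`, with
#' Gaussian load noise. The analytic values implied by the standard
#' definitions (10%-stiffness-loss yield, trapezoidal work to failure) are
#' recorded as ground truth.
#'
#' @param stiffness elastic slope, N/mm.
#' @param yield_load end of the elastic segment, N (< `ultimate_load`).
#' @param postyield_slope hardening slope, N/mm (< `stiffness`).
#' @param ultimate_load maximum load, N.
#' @param failure_displacement displacement at fracture, mm.
#' @param sample_rate sampling rate, Hz.
#' @param speed_mm_min crosshead speed, mm/min.
#' @param noise_sd load noise SD, N.
#' @param seed integer seed.
#' @return A `load_curve` with attribute `truth`: `stiffness`,
#'   `yield_load` (per the 10%-loss rule on the ideal curve),
#'   `ultimate_load`, `work_to_fracture`, `postyield_displacement`,
#'   `failure_displacement`.
#' @export
make_load_curve <- function(stiffness = 669, yield_load = 154,
                            postyield_slope = 150, ultimate_load = 211,
                            failure_displacement = 0.75,
                            sample_rate = 100, speed_mm_min = 0.5,
                            noise_sd = 0.2, seed = 1) {
  S <- stiffness; Y <- yield_load; k <- postyield_slope; U <- ultimate_load
  if (Y > U) stopf("`yield_load` must not exceed `ultimate_load`")
  if (k >= S) stopf("`postyield_slope` must be below `stiffness`")
  if (k < 0 || S <= 0) stopf("slopes must be positive (postyield >= 0)")
  if (k == 0 && U > Y)
    stopf("flat post-yield segment cannot reach `ultimate_load`: inconsistent parameters")
  dy <- Y / S
  du <- if (k > 0) dy + (U - Y) / k else dy
  if (du > failure_displacement)
    stopf("ultimate reached after `failure_displacement`: inconsistent parameters")
  ideal <- function(d) {
    ifelse(d <= dy, S * d,
           ifelse(d <= du, Y + k * (d - dy), U))
  }
  step <- speed_mm_min / 60 / sample_rate
  d <- seq(0, failure_displacement, by = step)
  load <- ideal(d)
  # abrupt failure drop after the recorded failure point
  d_post <- failure_displacement + step * (1:3)
  load_post <- U * c(0.05, 0.02, 0.01)
  d <- c(d, d_post)
  load <- c(load, load_post)
  if (noise_sd > 0)
    load <- load + with_seed(seed, rnorm(length(load), 0, noise_sd))
  # analytic 10%-stiffness-loss yield on the ideal curve
  dstar <- if (k > 0) Y * (S - k) / (S * (0.9 * S - k)) else Y / (0.9 * S)
  if (dstar <= du && k > 0) {
    yield_an <- 0.9 * S * dstar
    d_yield <- dstar
  } else {
    d_yield <- U / (0.9 * S)
    yield_an <- if (d_yield <= failure_displacement) U else NA_real_
  }
  work <- 0.5 * Y * dy + (du > dy) * 0.5 * (Y + U) * (du - dy) +
    U * (failure_displacement - du)
  truth <- list(stiffness = S, yield_load = yield_an,
                ultimate_load = U, work_to_fracture = work,
                postyield_displacement = failure_displacement - d_yield,
                failure_displacement = failure_displacement,
                d_yield = d_yield, seed = seed)
  cv <- load_curve(d, load, sample_rate = sample_rate)
  attr(cv, "truth") <- truth
  cv
}
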