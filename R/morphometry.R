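#' Static trabecular morphometry
#'
#' Bone volume fraction, model-independent local thickness and separation,
#' trabecular number, and volumetric BMD over a trabecular volume of
#' interest. Thickness and separation use the maximal-inscribed-sphere
#' (distance-transform) local thickness, averaged over bone and background
#' voxels respectively; Tb.N uses the direct plate-model definition
#' `1 / (Tb.Th + Tb.Sp)`.
#'
#' @param volume an HA-calibrated `density_volume` already cropped to the
#'   trabecular VOI.
#' @param mask optional `binary_mask` of bone; computed by thresholding at
#'   `threshold` when missing.
#' @param threshold trabecular segmentation threshold, mg/cm3.
#' @return An object of class `trabecular_morphometry`: `bvtv`, `tb_th_um`,
#'   `tb_sp_um`, `tb_n_mm`, `bmd_mg_cm3`.
#' @export
trabecular_metrics <- function(volume, mask = NULL, threshold = 300) {
  stopifnot(inherits(volume, "density_volume"))
  if (length(volume$values) == 0L) stopf("empty VOI")
  m <- if (is.null(mask)) segment_volume(volume, threshold)$mask else mask$mask
  vs <- volume$voxel_size_um
  bvtv <- mean(m)
  bmd <- mean(volume$values)
  if (!any(m)) {
    return(structure(list(bvtv = 0, tb_th_um = NA_real_, tb_sp_um = NA_real_,
                          tb_n_mm = 0, bmd_mg_cm3 = bmd),
                     class = "trabecular_morphometry"))
  }
  th <- local_thickness(m)
  tb_th <- mean(th[m]) * vs
  if (any(!m)) {
    sp <- local_thickness(!m)
    tb_sp <- mean(sp[!m]) * vs
    tb_n <- 1 / ((tb_th + tb_sp) / 1000)
  } else {
    tb_sp <- 0
    tb_n <- 1 / (tb_th / 1000)
  }
  structure(list(bvtv = bvtv, tb_th_um = tb_th, tb_sp_um = tb_sp,
                 tb_n_mm = tb_n, bmd_mg_cm3 = bmd),
            class = "trabecular_morphometry")
}

#' Static cortical morphometry of a diaphyseal ring
#'
#' Per-slice cross-sectional geometry averaged along the scan axis: total
#' area inside the filled periosteal boundary (Tt.Ar), bone area (Ct.Ar),
#' marrow area (Ma.Ar = Tt.Ar - Ct.Ar), cortical thickness by in-plane
#' local thickness, tissue mineral density over bone voxels (after a
#' one-voxel in-plane erosion to suppress partial-volume edges),
#' ellipse-equivalent major/minor axes and circularity of the filled
#' section, and the section modulus about the medio-lateral centroidal
#' axis for antero-posterior bending.
#'
#' @param volume an HA-calibrated `density_volume` cropped to the cortical
#'   VOI; the ring must be present in every slice.
#' @param mask optional bone `binary_mask`; thresholded at `threshold`
#'   when missing.
#' @param threshold cortical segmentation threshold, mg/cm3.
#' @param ap_axis image axis carrying the antero-posterior direction,
#'   `"y"` (default) or `"x"`; bending is about the perpendicular
#'   (medio-lateral) centroidal axis.
#' @return An object of class `cortical_morphometry` with fields `tt_ar_mm2`,
#'   `ct_ar_mm2`, `ma_ar_mm2`, `ct_ar_tt_ar`, `ct_th_mm`, `tmd_mg_cm3`,
#'   `major_axis_mm`, `minor_axis_mm`, `circularity`, `section_modulus_mm3`.
#' @export
cortical_metrics <- function(volume, mask = NULL, threshold = 700,
                             ap_axis = c("y", "x")) {
  stopifnot(inherits(volume, "density_volume"))
  ap_axis <- match.arg(ap_axis)
  m <- if (is.null(mask)) segment_volume(volume, threshold)$mask else mask$mask
  vs_mm <- volume$voxel_size_um / 1000
  nz <- dim(m)[3]
  if (!any(m)) stopf("no cortical bone above threshold")

  has_hole <- vapply(seq_len(nz), function(k) any(.holes_2d(m[, , k])), TRUE)
  if (any(has_hole) && any(!has_hole))
    stopf("broken cortical ring: marrow connected to background in slice %d",
          which(!has_hole)[1])

  per_slice <- lapply(seq_len(nz), function(k) {
    bone <- m[, , k]
    if (!any(bone)) stopf("no cortical bone in slice %d", k)
    filled <- .fill_holes_2d(bone)
    n_tt <- sum(filled)
    n_ct <- sum(bone)
    # moments of the filled section (voxel units, + 1/12 voxel self-moment)
    w <- which(filled, arr.ind = TRUE)
    mu <- colMeans(w)
    cxx <- mean((w[, 1] - mu[1])^2) + 1 / 12
    cyy <- mean((w[, 2] - mu[2])^2) + 1 / 12
    cxy <- mean((w[, 1] - mu[1]) * (w[, 2] - mu[2]))
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
    per <- perimeter_2d(filled)
    # bending about the ML centroidal axis; c along AP, from bone centroid
    wb <- which(bone, arr.ind = TRUE)
    ap <- if (ap_axis == "y") wb[, 2] else wb[, 1]
    apc <- ap - mean(ap)
    I_ml <- (sum(apc^2) + n_ct / 12) * vs_mm^4
    c_ap <- (max(abs(apc)) + 0.5) * vs_mm
    th <- local_thickness(bone)
    list(tt = n_tt * vs_mm^2, ct = n_ct * vs_mm^2,
         major = 4 * sqrt(max(ev)) * vs_mm, minor = 4 * sqrt(min(ev)) * vs_mm,
         circ = min(1, 4 * pi * n_tt / per^2),
         z = I_ml / c_ap, ct_th = mean(th[bone]) * vs_mm)
  })
  gm <- function(f) mean(vapply(per_slice, `[[`, 0, f))

  eroded <- m
  for (k in seq_len(nz)) eroded[, , k] <- erode(m[, , k], 1)
  tmd_mask <- if (any(eroded)) eroded else m
  tmd <- mean(volume$values[tmd_mask])

  tt <- gm("tt"); ct <- gm("ct")
  structure(list(tt_ar_mm2 = tt, ct_ar_mm2 = ct, ma_ar_mm2 = tt - ct,
                 ct_ar_tt_ar = ct / tt, ct_th_mm = gm("ct_th"),
                 tmd_mg_cm3 = tmd, major_axis_mm = gm("major"),
                 minor_axis_mm = gm("minor"), circularity = gm("circ"),
                 section_modulus_mm3 = gm("z")),
            class = "cortical_morphometry")
}

#' Abdominal adipose tissue quantification from a raw CT volume
#'
#' Calibrates the volume to Hounsfield units against air and water
#' standards, builds the body mask as the largest connected component above
#' an air cutoff, fills the abdominal outer perimeter slice by slice, erodes
#' the filled mask by `shell_erosion_mm` to exclude skin and subcutaneous
#' fat, and counts voxels whose HU fall inside the adipose window. The
#' percentage is adipose voxels over all tissue voxels of the eroded mask.
#'
#' @param volume a raw `density_volume`.
#' @param air_mean,water_mean raw grey values of the air and water
#'   standards.
#' @param hu_window adipose HU window, default `c(-280, -150)`.
#' @param shell_erosion_mm erosion depth excluding the subcutaneous shell.
#' @param air_hu_max HU cutoff separating body tissue from air background.
#' @return An object of class `adipose_result`: `adipose_voxels`,
#'   `tissue_voxels`, `percent_adipose`.
#' @export
adipose_fraction <- function(volume, air_mean, water_mean,
                             hu_window = c(-280, -150),
                             shell_erosion_mm = 1.0, air_hu_max = -400) {
  stopifnot(inherits(volume, "density_volume"))
  hu <- hu_calibrate(volume, air_mean, water_mean)
  body <- hu$values > air_hu_max
  if (!any(body)) stopf("empty body mask")
  body <- largest_component(body)
  body <- fill_holes_slicewise(body)
  r_vox <- shell_erosion_mm * 1000 / volume$voxel_size_um
  tissue <- erode(body, r_vox)
  if (!any(tissue)) stopf("erosion removed the whole body mask")
  adip <- tissue & hu$values >= hu_window[1] & hu$values <= hu_window[2]
  structure(list(adipose_voxels = sum(adip), tissue_voxels = sum(tissue),
                 percent_adipose = 100 * sum(adip) / sum(tissue)),
            class = "adipose_result")
}
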