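#' Calibrated density volume
#'
#' Container for a 3D scalar microCT field: voxel values, isotropic voxel
#' size, and the calibration state of the values. Values are `"raw"`
#' (scanner grey levels), `"HA"` (hydroxyapatite-equivalent density, mg/cm3)
#' or `"HU"` (Hounsfield units). Arrays are stored in `(x, y, z)` order with
#' `z` the scan axis, 1-based indices; slice `k` is `values[, , k]`.
#'
#' @param values numeric 3D array of voxel values.
#' @param voxel_size_um isotropic voxel size in micrometres (> 0).
#' @param calibration list with at least `type` (`"raw"`, `"HA"` or `"HU"`);
#'   calibration operations add their anchor points here.
#' @param landmark_slice optional slice index of an anatomical landmark
#'   (growth-plate proxy) used by volume-of-interest rules.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(values, voxel_size_um,
                           calibration = list(type = "raw"),
                           landmark_slice = NULL) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L || length(values) == 0L)
    stopf("`values` must be a non-empty 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stopf("`voxel_size_um` must be a single positive number")
  if (!is.list(calibration) || is.null(calibration$type) ||
      !calibration$type %in% c("raw", "HA", "HU"))
    stopf("`calibration$type` must be one of \"raw\", \"HA\", \"HU\"")
  structure(list(values = values, voxel_size_um = voxel_size_um,
                 calibration = calibration, landmark_slice = landmark_slice),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_volume> %d x %d x %d voxels, %.3g um, %s\n",
              d[1], d[2], d[3], x$voxel_size_um, x$calibration$type))
  invisible(x)
}

#' Binary voxel mask
#'
#' A logical mask on the same grid as its source volume.
#'
#' @param mask logical 3D array.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, voxel_size_um) {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stopf("`mask` must be a logical 3D array")
  structure(list(mask = mask, voxel_size_um = voxel_size_um),
            class = "binary_mask")
}

#' Two-point hydroxyapatite density calibration
#'
#' Affine calibration of raw grey values against two hydroxyapatite phantom
#' rods of known density (defaults 250 and 750 mg/cm3), sending the measured
#' phantom grey levels exactly onto their nominal densities.
#'
#' @param volume a raw `density_volume`.
#' @param low_raw,high_raw mean grey value measured in the low/high density
#'   phantom (`high_raw > low_raw`).
#' @param low_density,high_density nominal phantom densities in mg/cm3.
#' @return A `density_volume` with calibration type `"HA"` (mg/cm3).
#' @export
calibrate_density <- function(volume, low_raw, high_raw,
                              low_density = 250, high_density = 750) {
  stopifnot(inherits(volume, "density_volume"))
  if (high_raw <= low_raw) stopf("`high_raw` must exceed `low_raw`")
  slope <- (high_density - low_density) / (high_raw - low_raw)
  vals <- low_density + (volume$values - low_raw) * slope
  density_volume(vals, volume$voxel_size_um,
                 calibration = list(type = "HA", slope = slope,
                                    low_raw = low_raw, high_raw = high_raw,
                                    low_density = low_density,
                                    high_density = high_density),
                 landmark_slice = volume$landmark_slice)
}

#' Hounsfield-unit calibration against air and water standards
#'
#' Linear map sending the mean air grey value to -1000 HU and the mean
#' water grey value to 0 HU.
#'
#' @param volume a raw `density_volume`.
#' @param air_mean,water_mean mean grey values of the scanned air and water
#'   standards (`water_mean > air_mean`).
#' @return A `density_volume` with calibration type `"HU"`.
#' @export
hu_calibrate <- function(volume, air_mean, water_mean) {
  stopifnot(inherits(volume, "density_volume"))
  if (air_mean >= water_mean) stopf("`air_mean` must be below `water_mean`")
  vals <- 1000 * (volume$values - water_mean) / (water_mean - air_mean)
  density_volume(vals, volume$voxel_size_um,
                 calibration = list(type = "HU", air_mean = air_mean,
                                    water_mean = water_mean),
                 landmark_slice = volume$landmark_slice)
}

#' Global-threshold bone segmentation
#'
#' Thresholds a hydroxyapatite-calibrated volume at a density cutoff; the
#' conventional cutoffs are 300 mg/cm3 for trabecular and 700 mg/cm3 for
#' cortical bone.
#'
#' @param volume an HA-calibrated `density_volume`.
#' @param threshold density cutoff in mg/cm3; voxels with density >=
#'   threshold are bone.
#' @return A `binary_mask`.
#' @export
segment_volume <- function(volume, threshold = 300) {
  stopifnot(inherits(volume, "density_volume"))
  if (volume$calibration$type != "HA")
    stopf("segmentation requires an HA-calibrated volume, got \"%s\"",
          volume$calibration$type)
  binary_mask(volume$values >= threshold, volume$voxel_size_um)
}

#' Volume-of-interest specification relative to an anatomical landmark
#'
#' Describes a slab of slices along the scan axis, offset from a reference
#' slice (growth-plate proxy). With `centred = FALSE` the slab starts at the
#' offset and extends `extent_mm` in `direction`; with `centred = TRUE` the
#' offset locates the slab centre. Millimetre quantities are converted to
#' whole slices by rounding half away from zero; slice ranges are half-open
#' `[start, stop)` in 1-based indices.
#'
#' @param reference_slice landmark slice index (1-based).
#' @param offset_mm distance from the landmark to the slab (start or centre).
#' @param extent_mm slab length along the scan axis (> 0).
#' @param direction `+1` (increasing slice index) or `-1`.
#' @param centred logical; whether `offset_mm` locates the slab centre.
#' @return An object of class `voi_spec`.
#' @export
voi_spec <- function(reference_slice, offset_mm, extent_mm,
                     direction = 1, centred = FALSE) {
  if (extent_mm <= 0) stopf("`extent_mm` must be positive")
  if (!direction %in% c(-1, 1)) stopf("`direction` must be +1 or -1")
  structure(list(reference_slice = as.integer(reference_slice),
                 offset_mm = offset_mm, extent_mm = extent_mm,
                 direction = direction, centred = isTRUE(centred)),
            class = "voi_spec")
}

#' Resolve a VOI specification to a slice range and cropped volume
#'
#' @param volume a `density_volume`.
#' @param spec a [voi_spec()]; `NULL` selects the whole volume.
#' @return List with `start`, `stop` (half-open 1-based slice range),
#'   `n_slices`, and `volume`, the cropped `density_volume`.
#' @export
resolve_voi <- function(volume, spec) {
  stopifnot(inherits(volume, "density_volume"))
  nz <- dim(volume$values)[3]
  if (is.null(spec)) {
    return(list(start = 1L, stop = nz + 1L, n_slices = nz, volume = volume))
  }
  stopifnot(inherits(spec, "voi_spec"))
  vox_mm <- volume$voxel_size_um / 1000
  n_off <- as.integer(round_half_away(spec$offset_mm / vox_mm))
  n_ext <- as.integer(round_half_away(spec$extent_mm / vox_mm))
  if (n_ext < 1L) stopf("VOI extent resolves to zero slices")
  anchor <- spec$reference_slice + spec$direction * n_off
  if (spec$centred) {
    start <- anchor - n_ext %/% 2L
  } else if (spec$direction > 0) {
    start <- anchor
  } else {
    start <- anchor - n_ext + 1L
  }
  stop <- start + n_ext
  if (start < 1L || stop > nz + 1L)
    stopf("VOI slices [%d, %d) exit the volume (1..%d)", start, stop, nz)
  cropped <- density_volume(volume$values[, , start:(stop - 1L), drop = FALSE],
                            volume$voxel_size_um, volume$calibration)
  list(start = start, stop = stop, n_slices = n_ext, volume = cropped)
}

#' Slab VOI of n sections directly above a landmark
#'
#' Selects the half-open slice range `[landmark + 1, landmark + 1 + n)`,
#' i.e. exactly `n_sections` slices starting immediately above the landmark
#' (the abdominal convention: hip-bone landmark, 100 sections upward).
#'
#' @param volume a `density_volume`.
#' @param landmark_slice landmark slice index (1-based); defaults to the
#'   volume's stored landmark.
#' @param n_sections number of slices to keep.
#' @return Same shape of result as [resolve_voi()].
#' @export
slab_voi_above_landmark <- function(volume, landmark_slice = NULL,
                                    n_sections = 100) {
  stopifnot(inherits(volume, "density_volume"))
  landmark_slice <- landmark_slice %||% volume$landmark_slice
  if (is.null(landmark_slice)) stopf("no landmark slice available")
  nz <- dim(volume$values)[3]
  start <- as.integer(landmark_slice) + 1L
  stop <- start + as.integer(n_sections)
  if (n_sections < 1L || start < 1L || stop > nz + 1L)
    stopf("slab [%d, %d) exits the volume (1..%d)", start, stop, nz)
  cropped <- density_volume(volume$values[, , start:(stop - 1L), drop = FALSE],
                            volume$voxel_size_um, volume$calibration)
  list(start = start, stop = stop, n_slices = as.integer(n_sections),
       volume = cropped)
}

# ---- I/O: minimal uncompressed NIfTI-1 (.nii) + JSON sidecar ---------------
# No NIfTI/TIFF package is available in this stack, so the small fixed-layout
# NIfTI-1 header is read and written directly. float32 data, single file.

#' Write a density volume as NIfTI-1 with a JSON metadata sidecar
#'
#' @param volume a `density_volume`.
#' @param path output path ending in `.nii`; the sidecar is written next to
#'   it as `.json` and carries voxel size, calibration and landmark.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "density_volume"))
  d <- dim(volume$values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)                             # unused
  writeBin(as.integer(c(3, d, 1, 1, 1, 1)), con, size = 2)  # dim[8]
  writeBin(raw(14), con)                             # intent params etc.
  writeBin(c(16L, 32L), con, size = 2)               # datatype float32, bitpix
  writeBin(0L, con, size = 2)                        # slice_start
  mm <- volume$voxel_size_um / 1000
  writeBin(c(0, mm, mm, mm, 0, 0, 0, 0), con, size = 4)  # pixdim[8]
  writeBin(352, con, size = 4)                       # vox_offset
  writeBin(c(1, 0), con, size = 4)                   # scl_slope, scl_inter
  writeBin(raw(344 - 120), con)                      # remainder up to magic
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)      # magic at 344
  writeBin(raw(4), con)                              # pad to vox_offset 352
  writeBin(as.numeric(volume$values), con, size = 4)
  sidecar <- sub("\\.nii$", ".json", path)
  jsonlite::write_json(list(voxel_size_um = volume$voxel_size_um,
                            calibration = volume$calibration,
                            landmark_slice = volume$landmark_slice),
                       sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a density volume written by [write_volume()]
#'
#' @param path path to the `.nii` file; the `.json` sidecar is read from the
#'   same stem if present.
#' @return A `density_volume`.
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_sz <- readBin(con, "integer", 1, size = 4)
  if (!identical(hdr_sz, 348L)) stopf("not a NIfTI-1 file: %s", path)
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2)
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4)
  vox_offset <- readBin(con, "numeric", 1, size = 4)
  if (!datatype %in% c(16L, 64L)) stopf("unsupported NIfTI datatype %d", datatype)
  d <- dims[2:4]
  seek(con, vox_offset)
  vals <- readBin(con, "numeric", prod(d), size = if (datatype == 16L) 4 else 8)
  sidecar <- sub("\\.nii$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else list()
  density_volume(array(vals, d),
                 voxel_size_um = meta$voxel_size_um %||% (pixdim[2] * 1000),
                 calibration = as.list(meta$calibration %||% list(type = "raw")),
                 landmark_slice = meta$landmark_slice)
}
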