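# Shared fixtures and independent oracles built in code.

# brute-force voxelwise remodelling oracle: plain loop, no set algebra
remodel_bruteforce <- function(mo, mn) {
  n_common <- 0L; n_uo <- 0L; n_un <- 0L
  for (i in seq_along(mo)) {
    if (isTRUE(mo[i]) && isTRUE(mn[i])) n_common <- n_common + 1L
    else if (isTRUE(mo[i])) n_uo <- n_uo + 1L
    else if (isTRUE(mn[i])) n_un <- n_un + 1L
  }
  u <- n_common + n_uo + n_un
  list(n_common = n_common, n_unique_old = n_uo, n_unique_new = n_un,
       resorption_fraction = n_uo / u, formation_fraction = n_un / u)
}

# uniform HA-calibrated volume
uniform_volume <- function(value, dims = c(8, 8, 8), voxel_size_um = 18) {
  density_volume(array(value, dims), voxel_size_um,
                 calibration = list(type = "HA"))
}

# a raw volume with affine grey mapping, for calibration tests
raw_volume <- function(values, voxel_size_um = 18) {
  density_volume(values, voxel_size_um, calibration = list(type = "raw"))
}
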