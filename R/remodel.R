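#' Voxel-differencing bone formation and resorption fractions
#'
#' Compares two registered binary bone masks: voxels present only in the
#' older mask are resorption, voxels present only in the newer mask are
#' formation, and each fraction is the unique-voxel count divided by the
#' size of the union (common + unique voxels).
#'
#' @param mask_old,mask_new `binary_mask` objects (or logical arrays) on a
#'   common grid.
#' @param min_cluster optional minimum connected-cluster size (voxels) for
#'   unique-voxel regions; 0 (default) applies no filtering.
#' @return An object of class `remodel_result`: `n_common`, `n_unique_old`,
#'   `n_unique_new`, `n_union`, `resorption_fraction`, `formation_fraction`.
#' @export
remodel_fractions <- function(mask_old, mask_new, min_cluster = 0) {
  mo <- if (inherits(mask_old, "binary_mask")) mask_old$mask else mask_old
  mn <- if (inherits(mask_new, "binary_mask")) mask_new$mask else mask_new
  if (!identical(dim(mo), dim(mn))) stopf("mask shapes differ")
  # voxels outside either field of view (NA after resampling) are excluded
  valid <- !is.na(mo) & !is.na(mn)
  mo <- mo & valid
  mn <- mn & valid
  uo <- mo & !mn
  un <- mn & !mo
  if (min_cluster > 0) {
    drop_small <- function(m) {
      lab <- label_components(m)
      if (max(lab) == 0L) return(m)
      keep <- which(tabulate(lab[lab > 0L]) >= min_cluster)
      out <- lab %in% keep
      dim(out) <- dim(m)
      out
    }
    uo <- drop_small(uo)
    un <- drop_small(un)
  }
  n_common <- sum(mo & mn)
  n_uo <- sum(uo)
  n_un <- sum(un)
  n_union <- n_common + n_uo + n_un
  if (n_union == 0L) stopf("empty union of bone masks")
  structure(list(n_common = n_common, n_unique_old = n_uo,
                 n_unique_new = n_un, n_union = n_union,
                 resorption_fraction = n_uo / n_union,
                 formation_fraction = n_un / n_union),
            class = "remodel_result")
}

#' @export
print.remodel_result <- function(x, ...) {
  cat(sprintf("<remodel_result> union %d voxels: formation %.4f, resorption %.4f\n",
              x$n_union, x$formation_fraction, x$resorption_fraction))
  invisible(x)
}

#' Longitudinal remodelling pipeline on two calibrated volumes
#'
#' Registers the newer volume onto the older grid (optional), resolves the
#' volume of interest on both, segments at the density threshold, and
#' computes formation/resorption fractions by voxel differencing. Masks are
#' always recomputed by thresholding the resampled grey volume, never
#' interpolated.
#'
#' @param vol_old,vol_new HA-calibrated `density_volume`s.
#' @param voi a [voi_spec()] resolved on the old grid, or `NULL` for the
#'   whole volume.
#' @param threshold segmentation threshold in mg/cm3 (300 trabecular,
#'   700 cortical).
#' @param register run rigid registration of new onto old; set `FALSE` when
#'   the volumes are already on a common grid.
#' @param min_cluster passed to [remodel_fractions()].
#' @return A `remodel_result` with an added `transform` element (`NULL`
#'   when `register = FALSE`).
#' @export
remodel_pipeline <- function(vol_old, vol_new, voi = NULL, threshold = 300,
                             register = TRUE, min_cluster = 0) {
  stopifnot(inherits(vol_old, "density_volume"),
            inherits(vol_new, "density_volume"))
  transform <- NULL
  if (register) {
    reg <- register_rigid(vol_new, vol_old, threshold = threshold)
    vol_new <- reg$resampled
    transform <- reg$transform
  }
  cro <- resolve_voi(vol_old, voi)$volume
  crn <- resolve_voi(vol_new, voi)$volume
  res <- remodel_fractions(segment_volume(cro, threshold),
                           segment_volume(crn, threshold),
                           min_cluster = min_cluster)
  res$transform <- transform
  res
}

#' Percent change of a metric versus the previous timepoint
#'
#' Reports each timepoint's value as percent change from the immediately
#' preceding timepoint (not from baseline); the first timepoint has no
#' previous value and gets `NA`.
#'
#' @param values numeric metric values, one per timepoint (>= 2).
#' @param labels optional timepoint labels.
#' @return A data.frame with `timepoint`, `value`, `pct_change`.
#' @export
percent_change <- function(values, labels = NULL) {
  if (length(values) < 2L) stopf("need at least two timepoints")
  prev <- values[-length(values)]
  if (any(prev == 0)) stopf("zero value at a previous timepoint: percent change undefined")
  pc <- c(NA_real_, 100 * diff(values) / prev)
  data.frame(timepoint = labels %||% seq_along(values),
             value = values, pct_change = pc)
}
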