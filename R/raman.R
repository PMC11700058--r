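#' Raman spectrum container
#'
#' Wavenumber/intensity series on a strictly ascending grid (the working
#' range is 800-1800 cm-1).
#'
#' @param wavenumber numeric, cm-1, strictly ascending.
#' @param intensity numeric, same length.
#' @return An object of class `raman_spectrum` (a data.frame with columns
#'   `wavenumber` and `intensity`).
#' @export
raman_spectrum <- function(wavenumber, intensity) {
  if (length(wavenumber) != length(intensity))
    stopf("wavenumber and intensity lengths differ")
  if (any(diff(wavenumber) <= 0)) stopf("wavenumber grid must be strictly ascending")
  structure(data.frame(wavenumber = as.numeric(wavenumber),
                       intensity = as.numeric(intensity)),
            class = c("raman_spectrum", "data.frame"))
}

#' Read / write a spectrum as two-column CSV
#'
#' @param path CSV path with header `wavenumber_cm1,intensity`.
#' @param spectrum a `raman_spectrum`.
#' @return `read_spectrum()` returns a `raman_spectrum`; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  d <- read.csv(path)
  raman_spectrum(d[[1]], d[[2]])
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  write.csv(data.frame(wavenumber_cm1 = spectrum$wavenumber,
                       intensity = spectrum$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' Remove cosmic-ray spikes by nearest-neighbour replacement
#'
#' Channels whose second difference is an outlier (robust z-score above
#' `z_threshold`) are treated as cosmic rays and replaced by the mean of
#' the nearest unflagged neighbours on each side; all other channels are
#' untouched.
#'
#' @param spectrum a `raman_spectrum` with at least 16 channels.
#' @param z_threshold robust z-score cutoff on the second difference.
#' @return The despiked `raman_spectrum`.
#' @export
despike <- function(spectrum, z_threshold = 8) {
  y <- spectrum$intensity
  n <- length(y)
  if (n < 16L) stopf("need at least 16 channels")
  d2 <- c(0, diff(diff(y)), 0)
  s <- stats::mad(d2)
  # the z-score needs a noise floor; a (noiseless) spectrum whose typical
  # second difference is exactly zero has nothing to separate spikes from
  if (is.na(s) || s == 0) return(spectrum)
  flag <- abs(d2 - median(d2)) / s > z_threshold
  if (mean(flag) > 0.2)
    stopf("more than 20%% of channels flagged as spikes: spectrum unusable")
  if (!any(flag)) return(spectrum)
  idx_ok <- which(!flag)
  for (i in which(flag)) {
    lo <- idx_ok[idx_ok < i]
    hi <- idx_ok[idx_ok > i]
    nb <- c(if (length(lo)) max(lo), if (length(hi)) min(hi))
    y[i] <- mean(y[nb])
  }
  out <- raman_spectrum(spectrum$wavenumber, y)
  attr(out, "spikes") <- which(flag)
  out
}

#' Iterative polynomial baseline subtraction
#'
#' Fits a polynomial to the spectrum and iteratively excludes points lying
#' above the fit (beyond twice the robust noise estimate) until the
#' excluded set is stable, refitting the original values each round. Band
#' channels end up excluded, so the converged polynomial tracks the mean
#' background through the noise and band-free regions end up near zero
#' after subtraction.
#'
#' @param spectrum a `raman_spectrum`.
#' @param poly_order polynomial order (must be below `n/10`).
#' @param max_iter iteration cap; non-convergence is an error.
#' @return The baseline-corrected `raman_spectrum`, with the fitted
#'   baseline in attribute `baseline`.
#' @export
baseline_subtract <- function(spectrum, poly_order = 3, max_iter = 100) {
  x <- spectrum$wavenumber
  y <- spectrum$intensity
  if (poly_order >= length(y) / 10) stopf("`poly_order` too high for grid")
  u <- (x - mean(x)) / (diff(range(x)) / 2)
  X <- outer(u, 0:poly_order, `^`)
  keep <- rep(TRUE, length(y))
  converged <- FALSE
  beta <- qr.solve(X, y)
  floor_abs <- 1e-9 * (max(abs(y)) + 1)   # guards the noise-free fixed point
  base_prev <- NULL
  for (it in seq_len(max_iter)) {
    beta <- qr.solve(X[keep, , drop = FALSE], y[keep])
    base_it <- as.numeric(X %*% beta)
    res <- y - base_it
    sigma <- stats::mad(res[keep])
    new_keep <- res <= 2 * sigma + floor_abs
    if (sum(new_keep) <= poly_order + 1L) break  # degenerate: stop excluding
    if (identical(new_keep, keep) ||
        (!is.null(base_prev) && max(abs(base_it - base_prev)) <= floor_abs)) {
      converged <- TRUE
      break
    }
    keep <- new_keep
    base_prev <- base_it
  }
  if (!converged) stopf("baseline fit did not converge in %d iterations", max_iter)
  base <- as.numeric(X %*% beta)
  out <- raman_spectrum(x, y - base)
  attr(out, "baseline") <- base
  out
}

#' Band height within a window
#'
#' Maximum (baseline-corrected) intensity inside `[center - half_window,
#' center + half_window]`. The default window is 10 cm-1; the collagen
#' maturity pair at 1670/1690 cm-1 uses 5 cm-1 to keep its windows
#' disjoint. With `smooth_sigma > 0` the spectrum is first convolved with a
#' Gaussian kernel (sigma in channels) to suppress single-channel noise,
#' and — when the nominal band FWHM is supplied — the known peak
#' attenuation of a Gaussian band under that kernel is divided out, so the
#' estimate stays unbiased for a band of nominal width.
#'
#' @param spectrum a `raman_spectrum`.
#' @param center band centre, cm-1.
#' @param half_window half-width of the search window, cm-1.
#' @param smooth_sigma Gaussian denoising kernel sigma in channels
#'   (0 = plain window maximum).
#' @param nominal_fwhm nominal band FWHM in cm-1 used for the attenuation
#'   correction (ignored when `smooth_sigma = 0`).
#' @return The band height (numeric).
#' @export
band_height <- function(spectrum, center, half_window = 10,
                        smooth_sigma = 0, nominal_fwhm = NULL) {
  w <- spectrum$wavenumber
  if (center - half_window < min(w) || center + half_window > max(w))
    stopf("band window [%g, %g] outside the grid", center - half_window,
          center + half_window)
  y <- spectrum$intensity
  corr <- 1
  if (smooth_sigma > 0) {
    half <- max(1L, ceiling(3 * smooth_sigma))
    k <- exp(-(seq(-half, half))^2 / (2 * smooth_sigma^2))
    k <- k / sum(k)
    ys <- as.numeric(stats::filter(y, k, sides = 2))
    y <- ifelse(is.na(ys), y, ys)
    if (!is.null(nominal_fwhm)) {
      step <- median(diff(w))
      sn <- nominal_fwhm / (2 * sqrt(2 * log(2)))
      corr <- sqrt(sn^2 + (smooth_sigma * step)^2) / sn
    }
  }
  sel <- abs(w - center) <= half_window
  max(y[sel]) * corr
}

#' Subtract the embedding-resin contribution
#'
#' Scales the pMMA reference so that its ~812 cm-1 peak height matches the
#' spectrum's and subtracts it; the residual 812 cm-1 peak is zero by
#' construction. A negative scale is clamped to zero with a warning.
#'
#' @param spectrum a `raman_spectrum` (baseline-corrected).
#' @param pmma_ref the resin reference spectrum on the same grid; its
#'   dominant peak must lie near 812 cm-1.
#' @param smooth_sigma,nominal_fwhm height-estimation settings passed to
#'   [band_height()] (applied to both spectra, so the correction cancels in
#'   the scale).
#' @return The subtracted `raman_spectrum` with the scale in attribute
#'   `alpha`.
#' @export
pmma_subtract <- function(spectrum, pmma_ref, smooth_sigma = 0,
                          nominal_fwhm = NULL) {
  if (!isTRUE(all.equal(spectrum$wavenumber, pmma_ref$wavenumber)))
    stopf("spectrum and reference grids differ")
  pk <- pmma_ref$wavenumber[which.max(pmma_ref$intensity)]
  if (abs(pk - 812) > 15)
    stopf("reference dominant peak at %g cm-1, expected ~812", pk)
  h_ref <- band_height(pmma_ref, 812, 10, smooth_sigma, nominal_fwhm)
  alpha <- band_height(spectrum, 812, 10, smooth_sigma, nominal_fwhm) / h_ref
  if (alpha < 0) {
    warnf("negative resin scale %.3g clamped to 0", alpha)
    alpha <- 0
  }
  out <- raman_spectrum(spectrum$wavenumber,
                        spectrum$intensity - alpha * pmma_ref$intensity)
  attr(out, "alpha") <- alpha
  out
}

#' Full width at half maximum of the phosphate v1PO4 band
#'
#' Locates the 960 cm-1 peak and finds the half-maximum crossings on each
#' side by linear interpolation within +/- 40 cm-1.
#'
#' @param spectrum a baseline-corrected `raman_spectrum` with the 960 cm-1
#'   band above noise.
#' @return FWHM in cm-1; mineral crystallinity is its inverse.
#' @export
v1po4_fwhm <- function(spectrum) {
  w <- spectrum$wavenumber
  y <- spectrum$intensity
  sel <- which(abs(w - 960) <= 20)
  ipk <- sel[which.max(y[sel])]
  hm <- y[ipk] / 2
  if (y[ipk] <= 0) stopf("no v1PO4 band above zero")
  lim <- which(abs(w - w[ipk]) <= 40)
  lo <- NA_real_
  for (i in seq(ipk, max(min(lim), 2L), by = -1L)) {
    if (y[i] < hm) {
      lo <- w[i] + (w[i + 1] - w[i]) * (hm - y[i]) / (y[i + 1] - y[i])
      break
    }
  }
  hi <- NA_real_
  for (i in seq(ipk, min(max(lim), length(w) - 1L))) {
    if (y[i] < hm) {
      hi <- w[i - 1] + (w[i] - w[i - 1]) * (y[i - 1] - hm) / (y[i - 1] - y[i])
      break
    }
  }
  if (is.na(lo) || is.na(hi))
    stopf("half-maximum crossings not found within +/-40 cm-1 of the peak")
  hi - lo
}

#' Seven bone compositional parameters from a preprocessed spectrum
#'
#' Input must already be despiked and baseline-corrected. Nanoporosity
#' (812/960 height ratio) is computed BEFORE resin subtraction; the resin
#' component is then removed and the remaining parameters are measured on
#' the subtracted spectrum: mineral-to-matrix (960/Amide I at 1668),
#' carbonate-to-phosphate (1070/960), mineral crystallinity (1/FWHM of
#' 960), proline hydroxylation (872/854), glycosaminoglycan content
#' (1375/1245), and collagen maturity (1670/1690, 5 cm-1 windows).
#'
#' @param spectrum a despiked, baseline-corrected `raman_spectrum`.
#' @param pmma_ref resin reference spectrum on the same grid.
#' @param preprocess run [despike()] and [baseline_subtract()] first
#'   (convenience for raw input; default `FALSE` per the preprocessing
#'   contract).
#' @param smooth_sigma denoising kernel passed to [band_height()]; the
#'   default (3 channels) keeps height estimates stable against channel
#'   noise. Set to 0 for plain window maxima.
#' @param nominal_fwhm named vector of nominal band FWHMs (cm-1), typical
#'   of embedded cortical bone, used for the smoothing attenuation
#'   correction.
#' @return An object of class `raman_params`: `mmr`, `carb_phos`,
#'   `nanoporosity`, `crystallinity`, `hyp_pro`, `gag_amideIII`,
#'   `collagen_maturity`, plus the resin scale `pmma_alpha`.
#' @export
compute_params <- function(spectrum, pmma_ref, preprocess = FALSE,
                           smooth_sigma = 3,
                           nominal_fwhm = c(`812` = 10, `854` = 12,
                                            `872` = 12, `960` = 9.42,
                                            `1070` = 12, `1245` = 12,
                                            `1375` = 12, `1668` = 10,
                                            `1670` = 10, `1690` = 10)) {
  if (preprocess) {
    spectrum <- baseline_subtract(despike(spectrum))
  }
  h_of <- function(s, cn, hw = 10)
    band_height(s, cn, hw, smooth_sigma = smooth_sigma,
                nominal_fwhm = unname(nominal_fwhm[as.character(cn)]))
  nano <- h_of(spectrum, 812) / h_of(spectrum, 960)
  sub <- pmma_subtract(spectrum, pmma_ref, smooth_sigma = smooth_sigma,
                       nominal_fwhm = unname(nominal_fwhm["812"]))
  h <- function(cn, hw = 10) h_of(sub, cn, hw)
  fwhm <- v1po4_fwhm(sub)
  structure(list(mmr = h(960) / h(1668),
                 carb_phos = h(1070) / h(960),
                 nanoporosity = nano,
                 crystallinity = 1 / fwhm,
                 hyp_pro = h(872) / h(854),
                 gag_amideIII = h(1375) / h(1245),
                 collagen_maturity = h(1670, 5) / h(1690, 5),
                 pmma_alpha = attr(sub, "alpha")),
            class = "raman_params")
}

#' @export
print.raman_params <- function(x, ...) {
  cat(sprintf(paste0("<raman_params> MMR %.3g, CO3/PO4 %.3g, nanoporosity %.3g, ",
                     "crystallinity %.3g, Hyp/Pro %.3g, GAG/AmideIII %.3g, 1670/1690 %.3g\n"),
              x$mmr, x$carb_phos, x$nanoporosity, x$crystallinity,
              x$hyp_pro, x$gag_amideIII, x$collagen_maturity))
  invisible(x)
}

#' Distribution summary of a compositional parameter along a line scan
#'
#' Histograms the per-point parameter values, fits a Gaussian to the bin
#' counts by least squares, and reports the histogram-weighted mean
#' `sum(Xi * Fi) / sum(Fi)` (Xi bin centres, Fi bin fractions), the FWHM of
#' the fitted Gaussian (`2 sqrt(2 ln 2) * sigma`), and the fit R-squared.
#' The distribution is flagged normal when R-squared exceeds 0.95.
#'
#' @param values numeric parameter values along the periosteal-to-endosteal
#'   line (>= 20 points; exclude non-bone points first, see
#'   [linescan_params()]).
#' @param n_bins histogram bin count; `NULL` (default) uses Sturges' rule.
#' @return An object of class `distribution_summary`: `mean`, `fwhm`,
#'   `r2_gaussian`, `normal`, `n_points`, `n_bins`, `bin_edges`.
#' @export
linescan_summary <- function(values, n_bins = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20L) stopf("need at least 20 bone points, got %d", n)
  if (diff(range(values)) == 0)
    stopf("all values identical: degenerate histogram, Gaussian fit impossible")
  nb <- as.integer(n_bins %||% grDevices::nclass.Sturges(values))
  edges <- seq(min(values), max(values), length.out = nb + 1L)
  h <- graphics::hist(values, breaks = edges, plot = FALSE)
  xc <- h$mids
  f <- h$counts
  wmean <- sum(xc * f) / sum(f)
  st <- list(A = max(f), mu = wmean,
             sg = max(sd(values), diff(edges)[1]))
  fit <- tryCatch(
    suppressWarnings(
      nls(f ~ A * exp(-(xc - mu)^2 / (2 * sg^2)), start = st,
          control = nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) stopf("Gaussian fit failed on the histogram")
  co <- coef(fit)
  r2 <- 1 - sum(resid(fit)^2) / sum((f - mean(f))^2)
  structure(list(mean = wmean, fwhm = 2 * sqrt(2 * log(2)) * abs(co[["sg"]]),
                 r2_gaussian = r2, normal = r2 > 0.95, n_points = n,
                 n_bins = nb, bin_edges = edges),
            class = "distribution_summary")
}

#' Per-point compositional parameters along a cortical line scan
#'
#' Applies the point pipeline ([despike()], [baseline_subtract()],
#' [compute_params()]) to each spectrum of a periosteal-to-endosteal line
#' scan and excludes non-bone points by a mineral-to-matrix floor.
#'
#' @param spectra list of raw `raman_spectrum` objects in scan order.
#' @param pmma_ref resin reference spectrum.
#' @param mmr_floor points with mineral-to-matrix ratio below this are
#'   treated as non-bone and dropped.
#' @param poly_order baseline polynomial order.
#' @return A data.frame of parameters, one row per retained point, with
#'   attribute `n_excluded`.
#' @export
linescan_params <- function(spectra, pmma_ref, mmr_floor = 1.0,
                            poly_order = 3) {
  rows <- lapply(spectra, function(s) {
    p <- compute_params(baseline_subtract(despike(s), poly_order), pmma_ref)
    as.data.frame(unclass(p)[c("mmr", "carb_phos", "nanoporosity",
                               "crystallinity", "hyp_pro", "gag_amideIII",
                               "collagen_maturity")])
  })
  out <- do.call(rbind, rows)
  keep <- out$mmr >= mmr_floor
  res <- out[keep, , drop = FALSE]
  attr(res, "n_excluded") <- sum(!keep)
  res
}
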