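#' Load-displacement curve container
#'
#' Three-point-bending test trace: monotone non-decreasing displacement
#' (mm) and load (N), sampled at a fixed rate.
#'
#' @param displacement numeric, mm, monotone non-decreasing.
#' @param load numeric, N, same length (>= 50 samples).
#' @param sample_rate sampling rate, Hz.
#' @return An object of class `load_curve` (a data.frame with columns
#'   `displacement` and `load`).
#' @export
load_curve <- function(displacement, load, sample_rate = 100) {
  if (length(displacement) != length(load)) stopf("lengths differ")
  if (length(load) < 50L) stopf("need at least 50 samples")
  if (any(diff(displacement) < -1e-12))
    stopf("displacement must be monotone non-decreasing")
  structure(data.frame(displacement = as.numeric(displacement),
                       load = as.numeric(load)),
            sample_rate = sample_rate, class = c("load_curve", "data.frame"))
}

#' Read / write a bending curve as CSV with metadata header
#'
#' Two columns `displacement_mm,load_N`, preceded by `# key=value` comment
#' rows (e.g. `# span_mm=15`, `# rate_hz=100`).
#'
#' @param path CSV path.
#' @param curve a `load_curve`.
#' @param span_mm support span recorded in the header.
#' @return `read_load_curve()` returns a `load_curve` with attribute
#'   `span_mm` when present; `write_load_curve()` returns `path` invisibly.
#' @export
read_load_curve <- function(path) {
  hdr <- grep("^#", readLines(path, n = 20), value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- as.numeric(kv[2])
  }
  d <- read.csv(path, comment.char = "#")
  cv <- load_curve(d[[1]], d[[2]], sample_rate = meta$rate_hz %||% 100)
  attr(cv, "span_mm") <- meta$span_mm
  cv
}

#' @rdname read_load_curve
#' @export
write_load_curve <- function(curve, path, span_mm = 15) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# span_mm=%g", span_mm),
               sprintf("# rate_hz=%g", attr(curve, "sample_rate") %||% 100)),
             con)
  write.csv(data.frame(displacement_mm = curve$displacement,
                       load_N = curve$load),
            con, row.names = FALSE)
  invisible(path)
}

# trim machine-settling samples before the load first exceeds `preload_n`
# and re-zero displacement there
trim_preload <- function(curve, preload_n = 1) {
  i0 <- which(curve$load > preload_n)[1]
  if (is.na(i0) || i0 <= 1L) return(curve)
  out <- curve[i0:nrow(curve), ]
  out$displacement <- out$displacement - out$displacement[1]
  load_curve(out$displacement, out$load,
             sample_rate = attr(curve, "sample_rate") %||% 100)
}

#' Bending stiffness from the steepest pre-ultimate window
#'
#' Least-squares slope maximised over a sliding window spanning 20% of the
#' samples between 10% and 90% of the ultimate load, restricted to the
#' pre-ultimate part of the curve. An optional centred moving average
#' smooths the load before slope estimation (the raw curve is kept for
#' integration elsewhere).
#'
#' @param curve a `load_curve`.
#' @param window_frac sliding-window length as a fraction of the eligible
#'   samples.
#' @param smooth_width centred moving-average width in samples (0 or 1
#'   disables smoothing).
#' @return An object of class `stiffness_fit`: `stiffness` (N/mm),
#'   `intercept_d` (zero-load displacement intercept of the fit line),
#'   `window` (index range used).
#' @export
curve_stiffness <- function(curve, window_frac = 0.2, smooth_width = 5) {
  d <- curve$displacement
  y <- curve$load
  if (smooth_width > 1) {
    k <- rep(1 / smooth_width, smooth_width)
    ys <- as.numeric(stats::filter(y, k, sides = 2))
    y <- ifelse(is.na(ys), y, ys)
  }
  iu <- which.max(y)
  umax <- y[iu]
  elig <- which(seq_along(y) <= iu & y >= 0.1 * umax & y <= 0.9 * umax)
  if (length(elig) < 10L) stopf("fewer than 10 pre-yield samples")
  i1 <- min(elig); i2 <- max(elig)
  m <- i2 - i1 + 1L
  w <- max(10L, as.integer(ceiling(window_frac * m)))
  if (w > m) w <- m
  # rolling least-squares slope via cumulative sums
  cx <- cumsum(c(0, d)); cy <- cumsum(c(0, y))
  cxx <- cumsum(c(0, d^2)); cxy <- cumsum(c(0, d * y))
  starts <- i1:(i2 - w + 1L)
  ends <- starts + w - 1L
  n <- w
  sx <- cx[ends + 1L] - cx[starts]
  sy <- cy[ends + 1L] - cy[starts]
  sxx <- cxx[ends + 1L] - cxx[starts]
  sxy <- cxy[ends + 1L] - cxy[starts]
  denom <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / denom
  best <- which.max(slope)
  S <- slope[best]
  a <- (sy[best] - S * sx[best]) / n   # load intercept of the best fit
  structure(list(stiffness = S, intercept_d = -a / S,
                 window = c(starts[best], ends[best])),
            class = "stiffness_fit")
}

#' Yield point by the 10% stiffness-loss rule
#'
#' Constructs a line of slope `0.9 * S` anchored at the zero-load intercept
#' of the stiffness fit and finds its first crossing with the measured
#' curve after the linear region (linear interpolation between samples).
#' If the curve never crosses the line before failure, the ultimate point
#' is returned with `flagged = TRUE`.
#'
#' @param curve a `load_curve`.
#' @param stiffness a `stiffness_fit` from [curve_stiffness()], or a plain
#'   slope in N/mm (the intercept is then refit internally).
#' @return List `d_yield`, `yield_load`, `flagged`.
#' @export
yield_point <- function(curve, stiffness = curve_stiffness(curve)) {
  if (is.numeric(stiffness))
    stiffness <- list(stiffness = stiffness,
                      intercept_d = curve_stiffness(curve)$intercept_d,
                      window = curve_stiffness(curve)$window)
  S <- stiffness$stiffness
  if (S <= 0) stopf("stiffness must be positive")
  d <- curve$displacement
  y <- curve$load
  line <- 0.9 * S * (d - stiffness$intercept_d)
  start <- min(stiffness$window[2] + 1L, length(d))
  diffy <- y - line
  below <- which(diffy[start:length(d)] <= 0)
  if (length(below) == 0L) {
    iu <- which.max(y)
    return(list(d_yield = d[iu], yield_load = y[iu], flagged = TRUE))
  }
  j <- start + below[1] - 1L
  if (j == 1L) return(list(d_yield = d[1], yield_load = y[1], flagged = FALSE))
  # linear interpolation of the crossing between j-1 and j
  t <- diffy[j - 1] / (diffy[j - 1] - diffy[j])
  dy <- d[j - 1] + t * (d[j] - d[j - 1])
  list(d_yield = dy, yield_load = 0.9 * S * (dy - stiffness$intercept_d),
       flagged = FALSE)
}

#' Failure point, work to fracture and post-yield displacement
#'
#' Failure is the first sample whose load falls below `failure_frac` of the
#' running maximum (default 10%), or the last sample when no such drop
#' occurs. Work to fracture is the trapezoidal integral of the raw load
#' over displacement up to failure; post-yield displacement is the
#' displacement between yield and failure.
#'
#' @param curve a `load_curve`.
#' @param d_yield yield displacement (mm), e.g. from [yield_point()].
#' @param failure_frac fraction of the running maximum below which the
#'   specimen counts as fractured.
#' @return List `d_failure`, `work_to_fracture` (N mm),
#'   `postyield_displacement` (mm).
#' @export
failure_and_work <- function(curve, d_yield, failure_frac = 0.1) {
  d <- curve$displacement
  y <- curve$load
  runmax <- cummax(y)
  drop <- which(y < failure_frac * runmax & runmax > 0)
  ifail <- if (length(drop)) drop[1] else length(y)
  seg <- seq_len(ifail)
  work <- sum(diff(d[seg]) * (head(y[seg], -1) + tail(y[seg], -1)) / 2)
  list(d_failure = d[ifail], work_to_fracture = work,
       postyield_displacement = max(d[ifail] - d_yield, 0))
}

#' Peak bending moment and tissue strength
#'
#' For central loading in three-point bending the peak moment is
#' `F * L / 4`; tissue-level strength is the peak moment divided by the
#' section modulus (N mm / mm^3 = MPa).
#'
#' @param ultimate_load ultimate load F, N.
#' @param span support span L, mm (15 mm by convention here).
#' @param section_modulus section modulus Z of the bone cross-section about
#'   the bending axis, mm^3 (from [cortical_metrics()]).
#' @return List `peak_moment` (N mm), `tissue_strength` (MPa).
#' @export
bending_mechanics <- function(ultimate_load, span = 15, section_modulus) {
  if (ultimate_load <= 0 || span <= 0 || section_modulus <= 0)
    stopf("inputs must be positive")
  pm <- ultimate_load * span / 4
  list(peak_moment = pm, tissue_strength = pm / section_modulus)
}

#' Full structural + material analysis of a bending curve
#'
#' Preload-trims the curve, then derives stiffness, yield (10% stiffness
#' loss), ultimate point, failure, work to fracture, post-yield
#' displacement, and — when a section modulus is supplied — the peak moment
#' and tissue strength.
#'
#' @param curve a `load_curve`.
#' @param span support span, mm.
#' @param section_modulus section modulus, mm^3 (NA skips the material
#'   properties).
#' @param preload_n preload trim threshold, N.
#' @param failure_frac passed to [failure_and_work()].
#' @return An object of class `bending_result` with fields `ultimate_load`,
#'   `ultimate_displacement`, `yield_load`, `yield_flagged`, `stiffness`,
#'   `postyield_displacement`, `work_to_fracture`, `peak_moment`,
#'   `section_modulus`, `tissue_strength`, `span`.
#' @export
bending_analysis <- function(curve, span = 15, section_modulus = NA,
                             preload_n = 1, failure_frac = 0.1) {
  stopifnot(inherits(curve, "load_curve"))
  cv <- trim_preload(curve, preload_n)
  sf <- curve_stiffness(cv)
  yp <- yield_point(cv, sf)
  fw <- failure_and_work(cv, yp$d_yield, failure_frac)
  iu <- which.max(cv$load)
  res <- list(ultimate_load = cv$load[iu],
              ultimate_displacement = cv$displacement[iu],
              yield_load = yp$yield_load, yield_flagged = yp$flagged,
              stiffness = sf$stiffness,
              postyield_displacement = fw$postyield_displacement,
              work_to_fracture = fw$work_to_fracture,
              peak_moment = NA_real_, section_modulus = section_modulus,
              tissue_strength = NA_real_, span = span)
  if (is.finite(section_modulus)) {
    bm <- bending_mechanics(res$ultimate_load, span, section_modulus)
    res$peak_moment <- bm$peak_moment
    res$tissue_strength <- bm$tissue_strength
  }
  structure(res, class = "bending_result")
}

#' @export
print.bending_result <- function(x, ...) {
  cat(sprintf(paste0("<bending_result> ultimate %.1f N, yield %.1f N%s, ",
                     "stiffness %.0f N/mm, work %.1f N.mm\n"),
              x$ultimate_load, x$yield_load,
              if (x$yield_flagged) " (flagged)" else "", x$stiffness,
              x$work_to_fracture))
  invisible(x)
}
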