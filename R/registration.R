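#' Rigid 3D transform
#'
#' Proper rigid transform parameterised by three rotation angles in degrees
#' (applied as `Rz %*% Ry %*% Rx` about the volume centre) and a translation
#' in micrometres. The transform maps a point in fixed space to the
#' corresponding point in moving space (pull-back convention used for
#' resampling).
#'
#' @param angles_deg rotations about (z, y, x) in degrees.
#' @param translation_um translation (x, y, z) in micrometres.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0),
                            translation_um = c(0, 0, 0)) {
  stopifnot(length(angles_deg) == 3L, length(translation_um) == 3L)
  structure(list(angles_deg = as.numeric(angles_deg),
                 translation_um = as.numeric(translation_um)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (z,y,x) = %.3f, %.3f, %.3f deg; t = %.1f, %.1f, %.1f um\n",
              x$angles_deg[1], x$angles_deg[2], x$angles_deg[3],
              x$translation_um[1], x$translation_um[2], x$translation_um[3]))
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# Euler angles (z, y, x) in degrees from a rotation matrix, inverse of
# rotation_matrix() for |pitch| < 90 deg.
angles_from_matrix <- function(R) {
  beta <- asin(-R[3, 1])
  alpha <- atan2(R[2, 1], R[1, 1])
  gamma <- atan2(R[3, 2], R[3, 3])
  c(alpha, beta, gamma) * 180 / pi
}

#' Invert a rigid transform
#'
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform$angles_deg)
  Ri <- t(R)
  rigid_transform(angles_from_matrix(Ri),
                  as.numeric(-Ri %*% transform$translation_um))
}

#' Serialize / read a rigid transform as JSON
#'
#' @param transform a `rigid_transform`.
#' @param path JSON file path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   returns a `rigid_transform`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(angles_deg = transform$angles_deg,
                            translation_um = transform$translation_um),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$angles_deg, x$translation_um)
}

# Tricubic (Catmull-Rom) interpolation of `vals` at fractional voxel
# indices (1-based); edge voxels are replicated for the outer taps and
# points outside the grid return `fill`. Sharper edge recovery than
# trilinear, which matters when resampled volumes are re-thresholded.
tricubic <- function(vals, xi, yi, zi, fill = NA_real_) {
  d <- dim(vals)
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(fill, length(xi))
  if (!any(ok)) return(out)
  xi <- xi[ok]; yi <- yi[ok]; zi <- zi[ok]
  cr_w <- function(t) list(
    -0.5 * t^3 + t^2 - 0.5 * t,
    1.5 * t^3 - 2.5 * t^2 + 1,
    -1.5 * t^3 + 2 * t^2 + 0.5 * t,
    0.5 * t^3 - 0.5 * t^2)
  b <- function(v, n) pmin(pmax(v, 1L), n)
  x0 <- floor(xi); tx <- xi - x0
  y0 <- floor(yi); ty <- yi - y0
  z0 <- floor(zi); tz <- zi - z0
  wx <- cr_w(tx); wy <- cr_w(ty); wz <- cr_w(tz)
  acc <- numeric(length(xi))
  for (k in 1:4) {
    zk <- b(z0 + k - 2L, d[3])
    for (j in 1:4) {
      yj <- b(y0 + j - 2L, d[2])
      wyz <- wy[[j]] * wz[[k]]
      base <- ((zk - 1) * d[2] + (yj - 1)) * d[1]
      for (i in 1:4) {
        xi4 <- b(x0 + i - 2L, d[1])
        acc <- acc + wx[[i]] * wyz * vals[base + xi4]
      }
    }
  }
  out[ok] <- acc
  out
}

# Trilinear interpolation of `vals` (3D array) at fractional voxel indices
# (1-based). Points outside the grid return `fill`.
trilinear <- function(vals, xi, yi, zi, fill = NA_real_) {
  d <- dim(vals)
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(fill, length(xi))
  if (!any(ok)) return(out)
  xi <- xi[ok]; yi <- yi[ok]; zi <- zi[ok]
  x0 <- pmin(floor(xi), d[1] - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), d[2] - 1L); fy <- yi - y0
  z0 <- pmin(floor(zi), max(d[3] - 1L, 1L)); fz <- pmax(zi - z0, 0)
  if (d[3] == 1L) { z0 <- rep(1, length(xi)); fz <- rep(0, length(xi)) }
  idx <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
  v000 <- vals[idx(x0, y0, z0)]
  v100 <- vals[idx(x0 + 1, y0, z0)]
  v010 <- vals[idx(x0, y0 + 1, z0)]
  v110 <- vals[idx(x0 + 1, y0 + 1, z0)]
  z1 <- pmin(z0 + 1, d[3])
  v001 <- vals[idx(x0, y0, z1)]
  v101 <- vals[idx(x0 + 1, y0, z1)]
  v011 <- vals[idx(x0, y0 + 1, z1)]
  v111 <- vals[idx(x0 + 1, y0 + 1, z1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Resample a moving volume through a rigid transform
#'
#' For every voxel centre of the target grid the transform gives the
#' corresponding location in the moving volume, whose grey value is pulled
#' back by trilinear interpolation. Rotation is about the grid centre.
#'
#' @param moving a `density_volume`.
#' @param transform a `rigid_transform` mapping target (fixed) space to
#'   moving space.
#' @param grid_dim dimensions of the target grid (defaults to the moving
#'   volume's own grid).
#' @param fill value for voxels that fall outside the moving volume.
#' @param interp `"cubic"` (Catmull-Rom, default: sharper edges under
#'   re-thresholding) or `"linear"`.
#' @return A `density_volume` on the target grid.
#' @export
resample_volume <- function(moving, transform, grid_dim = dim(moving$values),
                            fill = 0, interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  stopifnot(inherits(moving, "density_volume"),
            inherits(transform, "rigid_transform"))
  vs <- moving$voxel_size_um
  d <- as.integer(grid_dim)
  ctr_f <- (d + 1) / 2
  ctr_m <- (dim(moving$values) + 1) / 2
  R <- rotation_matrix(transform$angles_deg)
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  p <- t(g) - ctr_f                       # voxel offsets from centre
  pm <- R %*% (p * vs) + transform$translation_um
  pm <- pm / vs + ctr_m
  fun <- if (interp == "cubic") tricubic else trilinear
  vals <- fun(moving$values, pm[1, ], pm[2, ], pm[3, ], fill = fill)
  density_volume(array(vals, d), vs, moving$calibration,
                 landmark_slice = moving$landmark_slice)
}

ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) return(NA_real_)
  suppressWarnings(cor(a[ok], b[ok]))
}

#' Rigid registration of two density volumes
#'
#' Two-stage scheme: (1) coarse alignment from the centroid and, when the
#' structure is sufficiently anisotropic, the principal axes of the
#' thresholded structure; (2) local rigid refinement maximising the
#' normalised cross-correlation (NCC) of the calibrated grey values
#' (Nelder-Mead over three angles and three translations). Segmentation is
#' meant to happen after resampling: the returned volume is grey-valued.
#'
#' @param moving,fixed `density_volume`s on grids with equal voxel size.
#' @param threshold density threshold (same units as the volumes) defining
#'   the structure used for the coarse stage.
#' @param refine run the NCC refinement stage (stage 2).
#' @param maxit maximum Nelder-Mead iterations.
#' @return List with `transform` (fixed-to-moving `rigid_transform`),
#'   `resampled` (moving volume on the fixed grid; voxels outside the
#'   moving field of view are `NA`), `ncc` achieved, and `ncc_initial`
#'   before refinement.
#' @export
register_rigid <- function(moving, fixed, threshold = 300, refine = TRUE,
                           maxit = 400) {
  stopifnot(inherits(moving, "density_volume"),
            inherits(fixed, "density_volume"))
  if (abs(moving$voxel_size_um - fixed$voxel_size_um) > 1e-9)
    stopf("voxel sizes differ")
  vs <- fixed$voxel_size_um
  mm <- moving$values >= threshold
  mf <- fixed$values >= threshold
  if (!any(mm) || !any(mf)) stopf("empty threshold mask, cannot register")

  cen <- function(mask) {
    w <- which(mask, arr.ind = TRUE)
    colMeans(w)
  }
  axes <- function(mask) {
    w <- which(mask, arr.ind = TRUE)
    e <- eigen(cov(w), symmetric = TRUE)
    list(values = e$values, vectors = e$vectors)
  }
  cm <- cen(mm); cf <- cen(mf)
  am <- axes(mm); af <- axes(mf)
  # principal axes are only trustworthy when eigenvalues are well separated
  gap <- min(af$values[1] / af$values[2], af$values[2] / af$values[3],
             am$values[1] / am$values[2], am$values[2] / am$values[3])
  R0 <- diag(3)
  if (is.finite(gap) && gap > 1.15) {
    Vf <- af$vectors; Vm <- am$vectors
    # resolve sign ambiguity: pick signs giving the rotation nearest identity
    best <- NULL
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      R <- Vm %*% diag(c(s1, s2, 1)) %*% t(Vf)
      if (det(R) < 0) R <- Vm %*% diag(c(s1, s2, -1)) %*% t(Vf)
      if (is.null(best) || sum(diag(R)) > sum(diag(best))) best <- R
    }
    R0 <- best
  }
  ctr_f <- (dim(fixed$values) + 1) / 2
  ctr_m <- (dim(moving$values) + 1) / 2
  # fixed-space point p (centre-relative, um) maps to R0 p + t0
  t0 <- ((cm - ctr_m) - R0 %*% (cf - ctr_f)) * vs
  tf0 <- rigid_transform(angles_from_matrix(R0), as.numeric(t0))

  # NCC scored on a stride-subsampled grid for speed; final resample is full
  d <- dim(fixed$values)
  stride <- max(1L, floor(min(d) / 24))
  sub <- expand.grid(x = seq(1L, d[1], by = stride),
                     y = seq(1L, d[2], by = stride),
                     z = seq(1L, d[3], by = stride))
  fsub <- fixed$values[as.matrix(sub)]
  psub <- t(as.matrix(sub)) - ctr_f
  score <- function(par) {
    R <- rotation_matrix(par[1:3])
    pm <- (R %*% (psub * vs) + par[4:6] * vs) / vs + ctr_m
    -ncc(trilinear(moving$values, pm[1, ], pm[2, ], pm[3, ]), fsub)
  }
  par0 <- c(tf0$angles_deg, tf0$translation_um / vs)
  ncc0 <- -score(par0)
  best_par <- par0
  ncc_best <- ncc0
  if (refine) {
    opt <- optim(par0, score, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    # restart at the optimum: a fresh simplex escapes premature collapse
    opt <- optim(opt$par, score, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    if (is.finite(opt$value) && -opt$value > ncc0) {
      best_par <- opt$par
      ncc_best <- -opt$value
    } else {
      warnf("NCC refinement did not improve on the coarse alignment; keeping stage-1 result")
    }
    # trimmed polish: voxels that genuinely changed between the scans
    # (remodelling) are high-residual outliers that bias the plain NCC
    # optimum, so re-optimise on the best-matching 90% only
    for (round in 1:2) {
      R <- rotation_matrix(best_par[1:3])
      pm <- (R %*% (psub * vs) + best_par[4:6] * vs) / vs + ctr_m
      mv <- trilinear(moving$values, pm[1, ], pm[2, ], pm[3, ])
      ok <- is.finite(mv) & is.finite(fsub)
      if (sum(ok) < 100) break
      sm <- sd(mv[ok]); sf <- sd(fsub[ok])
      resid <- abs((mv - mean(mv[ok])) / sm - (fsub - mean(fsub[ok])) / sf)
      keep <- ok & resid <= quantile(resid[ok], 0.9)
      tscore <- function(par) {
        R <- rotation_matrix(par[1:3])
        pm <- (R %*% (psub * vs) + par[4:6] * vs) / vs + ctr_m
        -ncc(trilinear(moving$values, pm[1, ], pm[2, ], pm[3, ])[keep],
             fsub[keep])
      }
      opt <- optim(best_par, tscore, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
      best_par <- opt$par
    }
    ncc_best <- -score(best_par)
  }
  transform <- rigid_transform(best_par[1:3], best_par[4:6] * vs)
  resampled <- resample_volume(moving, transform, grid_dim = dim(fixed$values),
                               fill = NA_real_)
  list(transform = transform, resampled = resampled,
       ncc = ncc_best, ncc_initial = ncc0)
}
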