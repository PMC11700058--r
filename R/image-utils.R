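# Low-level voxel utilities shared by the imaging modules. All operate on
# plain logical/numeric arrays in (x, y, z) order; distances are in voxel
# units unless stated otherwise. The heavy kernels (exact Euclidean distance
# transform, maximal-sphere local thickness, BFS component labelling) live
# in src/.

.dim3 <- function(a) {
  d <- dim(a)
  if (is.null(d)) stopf("expected an array")
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) != 3L) stopf("expected a 2D or 3D array")
  as.integer(d)
}

# Euclidean distance (voxel units) of TRUE voxels to the nearest FALSE voxel
# centre. 2D inputs are handled as single-slice volumes.
edt <- function(mask) {
  d <- .dim3(mask)
  out <- sqrt(.edt_sq(as.logical(mask), d))
  dim(out) <- dim(mask)
  out
}

# Local thickness map (voxel units): diameter of the largest inscribed
# sphere (disk in 2D) containing each foreground voxel.
local_thickness <- function(mask) {
  d <- .dim3(mask)
  m <- as.logical(mask)
  th <- .local_thickness(m, .edt_sq(m, d), d)
  dim(th) <- dim(mask)
  th
}

label_components <- function(mask) {
  d <- .dim3(mask)
  lab <- .label_components(as.logical(mask), d)
  dim(lab) <- dim(mask)
  lab
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(array(FALSE, dim(mask)))
  tab <- tabulate(lab[lab > 0L])
  out <- lab == which.max(tab)
  dim(out) <- dim(mask)
  out
}

# Morphology through the distance transform: erosion strips a boundary band
# of depth r voxels, dilation adds one.
erode <- function(mask, r) {
  out <- mask & (edt(mask) > r)
  dim(out) <- dim(mask)
  out
}

dilate <- function(mask, r) {
  out <- mask | (edt(!mask) <= r)
  dim(out) <- dim(mask)
  out
}

# Fill enclosed holes slice by slice (z = third dimension): background
# components not reaching the slice border are interior and get filled.
fill_holes_slicewise <- function(mask) {
  d <- .dim3(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- if (length(dim(mask)) == 3L) mask[, , k] else mask
    filled <- .fill_holes_2d(sl)
    if (length(dim(mask)) == 3L) out[, , k] <- filled else out <- filled
  }
  out
}

.fill_holes_2d <- function(sl) {
  lab <- label_components(!sl)
  if (max(lab) == 0L) return(sl)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  sl | !(lab %in% c(0L, border))
}

# holes of a 2D slice (marrow detector): filled minus foreground
.holes_2d <- function(sl) .fill_holes_2d(sl) & !sl

# Separable Gaussian smoothing with circular (periodic) boundary, used by
# the random-field phantom generators. sigma in voxels.
gauss_smooth3 <- function(a, sigma) {
  d <- .dim3(a)
  sm1 <- function(m) {
    n <- nrow(as.matrix(m))
    # kernel must fit the (circular) series length
    half <- min(max(1L, ceiling(3 * sigma)), (n - 1L) %/% 2L)
    if (half < 1L) return(m)
    kx <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    kx <- kx / sum(kx)
    stats::filter(m, kx, sides = 2, circular = TRUE)
  }
  a <- array(a, d)
  # x direction: dim 1 varies fastest, filter() works columnwise
  a <- array(sm1(matrix(a, d[1], d[2] * d[3])), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(sm1(matrix(a, d[2], d[1] * d[3])), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  if (d[3] > 1L) {
    a <- aperm(a, c(3, 2, 1))
    a <- array(sm1(matrix(a, d[3], d[2] * d[1])), c(d[3], d[2], d[1]))
    a <- aperm(a, c(3, 2, 1))
  }
  a
}

# Moore-neighbour tracing of the outer boundary of the largest foreground
# region of a 2D mask. Returns an n x 2 matrix of pixel-centre coordinates
# (x, y) ordered along the closed contour.
trace_contour <- function(sl) {
  if (!any(sl)) stopf("empty mask, no contour to trace")
  nb <- matrix(c(-1L, 0L, -1L, -1L, 0L, -1L, 1L, -1L,
                 1L, 0L, 1L, 1L, 0L, 1L, -1L, 1L), ncol = 2, byrow = TRUE)
  nx <- nrow(sl); ny <- ncol(sl)
  at <- function(i, j) i >= 1L && i <= nx && j >= 1L && j <= ny && sl[i, j]
  # start: first foreground pixel in raster order; its -x neighbour is bg
  idx <- which(sl)[1]
  si <- (idx - 1L) %% nx + 1L
  sj <- (idx - 1L) %/% nx + 1L
  path <- matrix(0L, 4L * sum(sl) + 8L, 2L)
  path[1, ] <- c(si, sj)
  np <- 1L
  # backtrack direction: index into nb pointing at the last background pixel
  bdir <- 1L  # came from -x
  ci <- si; cj <- sj
  first_move <- NA_integer_
  repeat {
    found <- FALSE
    for (s in 1:8) {
      k <- (bdir - 1L + s - 1L) %% 8L + 1L
      ii <- ci + nb[k, 1]; jj <- cj + nb[k, 2]
      if (at(ii, jj)) {
        # new backtrack: neighbour scanned just before the hit
        bprev <- (k - 2L) %% 8L + 1L
        pi <- ci + nb[bprev, 1]; pj <- cj + nb[bprev, 2]
        bdir <- which(nb[, 1] == (pi - ii) & nb[, 2] == (pj - jj))
        ci <- ii; cj <- jj
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (is.na(first_move)) first_move <- k
    np <- np + 1L
    if (np > nrow(path)) break
    path[np, ] <- c(ci, cj)
    if (ci == si && cj == sj) {
      np <- np - 1L  # closed: drop duplicate of start
      break
    }
  }
  path[seq_len(max(np, 1L)), , drop = FALSE]
}

# Perimeter (in voxel units) of the largest region of a binary slice:
# traced pixel-centre contour, circular moving-average smoothing to remove
# digitisation staircase, plus the half-voxel outward offset (Steiner term
# 2*pi*0.5) so a digitised disk recovers 2*pi*R.
perimeter_2d <- function(sl, smooth_window = 7L) {
  p <- trace_contour(sl)
  n <- nrow(p)
  if (n < 8L) return(n * 1.0)  # tiny region: crude
  w <- min(as.integer(smooth_window), (n %/% 4L) * 2L + 1L)
  if (w >= 3L) {
    k <- rep(1 / w, w)
    px <- stats::filter(p[, 1], k, sides = 2, circular = TRUE)
    py <- stats::filter(p[, 2], k, sides = 2, circular = TRUE)
    p <- cbind(as.numeric(px), as.numeric(py))
  }
  dseg <- sqrt(diff(c(p[, 1], p[1, 1]))^2 + diff(c(p[, 2], p[1, 2]))^2)
  sum(dseg) + pi  # + 2*pi*(1/2 voxel) outward offset
}
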