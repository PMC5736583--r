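#' Image preprocessing chain for DIC movies
#'
#' The standard processing order for a Z-scanned DIC time-lapse is: expand
#' the camera range, cancel XY stage drift, correct piezo Z-positioning
#' errors, convert with the composite RT filter, smooth spatiotemporally,
#' and resample the Z axis to isotropic voxels. Each step is an independent
#' function operating on plain arrays (`[x, y, z]` stacks or
#' `[x, y, z, t]` / `[x, y, t]` movies).
#'
#' @name preprocessing
NULL

#' Expand intensity to the full 12-bit range
#'
#' Linear map of the global minimum/maximum of the whole sequence onto
#' `[0, 4095]` (one global scale, so relative intensities across frames are
#' preserved).
#'
#' @param movie numeric array.
#' @return Array of the same shape.
#' @export
expand_range <- function(movie) {
  r <- range(movie)
  if (r[1] == r[2]) stop("constant input: intensity scale undefined")
  out <- (movie - r[1]) / (r[2] - r[1]) * 4095
  attributes(out) <- attributes(movie)
  out
}

#' Subpixel translation between two planes
#'
#' Symmetric phase-only matched filtering: the cross-power spectrum is
#' whitened by its own magnitude, so the correlation surface is a sharp
#' peak at the translation. The integer peak is refined to subpixel
#' precision by a separable 3-point quadratic fit. The peak height (1 for a
#' pure shift, smaller under noise or mismatch) is returned as a
#' confidence; below `conf_floor` the estimate is flagged.
#'
#' @param planeA,planeB numeric matrices of identical shape.
#' @param conf_floor minimum acceptable correlation peak (default 0.03).
#' @return Numeric `c(dx, dy)` such that `planeB` is `planeA` translated by
#'   `(dx, dy)`; attributes `confidence` and `low_confidence`.
#' @export
estimate_shift <- function(planeA, planeB, conf_floor = 0.03) {
  if (!all(dim(planeA) == dim(planeB))) stop("planes must share a shape")
  FA <- stats::fft(planeA)
  FB <- stats::fft(planeB)
  X <- FA * Conj(FB)
  mag <- Mod(X)
  mag[mag < 1e-300] <- 1
  R <- X / mag
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  n <- dim(r)
  # quadratic subpixel refinement per axis around the integer peak
  sub <- numeric(2)
  for (ax in 1:2) {
    im <- pk; ip <- pk
    im[ax] <- ((pk[ax] - 2) %% n[ax]) + 1
    ip[ax] <- (pk[ax] %% n[ax]) + 1
    cm <- r[im[1], im[2]]; c0 <- r[pk[1], pk[2]]; cp <- r[ip[1], ip[2]]
    den <- cm - 2 * c0 + cp
    sub[ax] <- if (abs(den) > 1e-300) (cm - cp) / (2 * den) else 0
    sub[ax] <- max(-0.5, min(0.5, sub[ax]))
  }
  p0 <- pk - 1 + sub
  p0 <- ifelse(p0 > n / 2, p0 - n, p0)
  s <- -p0
  structure(s, confidence = max(r),
            low_confidence = max(r) < conf_floor)
}

#' Cancel XY stage drift over a movie
#'
#' For each pair of successive frames the plane-wise shift is estimated
#' over all Z planes ([estimate_shift()]); the mean over Z is taken as the
#' stage drift for that interval. Cumulative drift is subtracted from every
#' plane by subpixel Fourier resampling. Frames whose plane-wise estimates
#' are mostly low-confidence inherit the drift interpolated from their
#' neighbours.
#'
#' @param movie 4D array `[x, y, z, t]` (a 3D array is treated as a 2D
#'   movie `[x, y, t]`).
#' @return Corrected movie; attribute `drift` holds the per-frame
#'   cumulative drift (frames x 2, pixels).
#' @export
correct_xy_drift <- function(movie) {
  d <- dim(movie)
  if (length(d) == 3) movie <- array(movie, c(d[1], d[2], 1, d[3]))
  dd <- dim(movie)
  nt <- dd[4]; nz <- dd[3]
  if (nt < 2) stop("need at least 2 frames")
  step <- matrix(0, nt, 2)
  ok <- rep(TRUE, nt)
  for (t in 2:nt) {
    sh <- matrix(0, nz, 2); conf <- logical(nz)
    for (z in seq_len(nz)) {
      s <- estimate_shift(movie[, , z, t - 1], movie[, , z, t])
      sh[z, ] <- s
      conf[z] <- !attr(s, "low_confidence")
    }
    if (mean(conf) >= 0.5) {
      step[t, ] <- colMeans(sh[conf, , drop = FALSE])
    } else ok[t] <- FALSE
  }
  # interpolate drift steps for flagged frames
  if (any(!ok[-1])) {
    for (c2 in 1:2)
      step[!ok, c2] <- stats::approx(which(ok), step[ok, c2],
                                     xout = which(!ok), rule = 2)$y
  }
  drift <- apply(step, 2, cumsum)
  out <- movie
  for (t in 2:nt) for (z in seq_len(nz))
    out[, , z, t] <- fourier_shift(movie[, , z, t], -drift[t, ])
  if (length(d) == 3) out <- array(out, d)
  attributes(out)[names(attributes(movie))] <- attributes(movie)
  dim(out) <- d
  attr(out, "drift") <- drift
  attr(out, "drift_flagged") <- which(!ok)
  out
}

# Lagrange interpolation of stack planes at fractional position `pos`,
# skipping plane `skip` (used as the Z-correction objective).
predict_plane <- function(stack, skip, pos) {
  nz <- dim(stack)[3]
  nb <- setdiff(pmin(pmax(seq(skip - 2, skip + 2), 1), nz), skip)
  nb <- unique(nb)
  if (length(nb) > 4) nb <- nb[order(abs(nb - pos))][1:4]
  # Lagrange weights on the neighbour positions
  w <- vapply(seq_along(nb), function(j) {
    prod((pos - nb[-j]) / (nb[j] - nb[-j]))
  }, numeric(1))
  out <- array(0, dim(stack)[1:2])
  for (j in seq_along(nb)) out <- out + w[j] * stack[, , nb[j]]
  out
}

#' Correct plane positioning errors along Z
#'
#' Each plane's axial offset (in plane spacings, bounded to
#' `[-0.5, +0.5]`) is found by minimizing the mean square difference
#' between the plane and the Lagrange interpolation of its neighbouring
#' planes evaluated at the candidate position. The stack is then resampled
#' at the nominal integer positions by linear interpolation between the
#' measured (offset) plane positions.
#'
#' @param stack 3D array `[x, y, z]` with at least 3 planes.
#' @return Corrected stack; attributes `z_offsets` (per-plane offsets) and
#'   `z_flagged` (planes where the objective did not improve on zero
#'   offset; their offset is kept at 0).
#' @export
correct_z_positions <- function(stack) {
  nz <- dim(stack)[3]
  if (nz < 3) stop("need at least 3 planes")
  offs <- numeric(nz)
  flagged <- logical(nz)
  for (i in 2:(nz - 1)) {
    obj <- function(delta) mean((stack[, , i] -
                                   predict_plane(stack, i, i + delta))^2)
    opt <- stats::optimize(obj, c(-0.5, 0.5))
    if (opt$objective <= obj(0)) offs[i] <- opt$minimum else flagged[i] <- TRUE
  }
  pos <- seq_len(nz) + offs
  out <- stack
  for (i in seq_len(nz)) {
    j <- findInterval(i, pos, all.inside = TRUE)
    w <- (i - pos[j]) / (pos[j + 1] - pos[j])
    w <- max(0, min(1, w))
    out[, , i] <- (1 - w) * stack[, , j] + w * stack[, , j + 1]
  }
  attr(out, "z_offsets") <- offs
  attr(out, "z_flagged") <- which(flagged)
  out
}

#' Spatiotemporal Gaussian smoothing
#'
#' Separable Gaussian along X, Y and time only (never Z). Kernels are
#' normalized to unit DC gain and applied circularly, so total intensity is
#' preserved.
#'
#' @param movie `[x, y, t]` or `[x, y, z, t]` array.
#' @param sx,sy,st standard deviations (pixels / frames); 0 disables an
#'   axis.
#' @return Smoothed array of identical shape.
#' @export
smooth_spatiotemporal <- function(movie, sx = 1, sy = 1, st = 1) {
  stopifnot(sx >= 0, sy >= 0, st >= 0)
  nd <- length(dim(movie))
  if (!nd %in% 3:4) stop("movie must be a 3D or 4D array")
  tdim <- nd
  out <- movie
  out <- gaussian_blur(out, c(sx, sy), dims = 1:2, boundary = "circular")
  out <- gaussian_blur(out, st, dims = tdim, boundary = "circular")
  attributes(out) <- attributes(movie)
  out
}

# Catmull-Rom cardinal weights at fraction f in [0, 1).
catmull_rom_w <- function(f) {
  0.5 * c(-f^3 + 2 * f^2 - f,
          3 * f^3 - 5 * f^2 + 2,
          -3 * f^3 + 4 * f^2 + f,
          f^3 - f^2)
}

#' Resample a stack to isotropic voxels along Z
#'
#' Interpolates `z_upsample` planes per original Z interval with a
#' Catmull-Rom cubic (clamped at the boundary planes), e.g. 250 nm Z
#' spacing with fourfold upsampling becomes 62.5 nm, matching a 64.5 nm XY
#' pitch closely enough for voxel-wise analysis.
#'
#' @param stack `[x, y, z]` or `[x, y, z, t]` array; attribute `pitch_nm`
#'   (length 3) updated when present.
#' @param z_upsample integer upsampling factor (1 = identity).
#' @return Resampled array with `(nz - 1) * z_upsample + 1` planes.
#' @export
resample_isotropic <- function(stack, z_upsample = 4) {
  z_upsample <- as.integer(z_upsample)
  stopifnot(z_upsample >= 1)
  p <- attr(stack, "pitch_nm")
  dt <- attr(stack, "dt_s")
  d <- dim(stack)
  had_t <- length(d) == 4
  if (z_upsample == 1) return(stack)
  if (!had_t) { stack <- array(stack, c(d, 1)) }
  dd <- dim(stack)
  nz <- dd[3]
  # virtual boundary planes by clamped linear extrapolation (keeps the
  # interpolator exact on linear-in-z data out to the stack ends)
  plane_at <- function(t, j) {
    if (j < 1) return(2 * stack[, , 1, t] - stack[, , 2, t])
    if (j > nz) return(2 * stack[, , nz, t] - stack[, , nz - 1, t])
    stack[, , j, t]
  }
  zq <- seq(1, nz, by = 1 / z_upsample)
  out <- array(0, c(dd[1], dd[2], length(zq), dd[4]))
  for (q in seq_along(zq)) {
    j <- min(floor(zq[q]), nz - 1)
    f <- zq[q] - j
    w <- catmull_rom_w(f)
    for (t in seq_len(dd[4])) {
      out[, , q, t] <- w[1] * plane_at(t, j - 1) + w[2] * plane_at(t, j) +
        w[3] * plane_at(t, j + 1) + w[4] * plane_at(t, j + 2)
    }
  }
  if (!had_t) out <- array(out, dim(out)[1:3])
  if (!is.null(p)) attr(out, "pitch_nm") <- c(p[1:2], p[3] / z_upsample)
  if (!is.null(dt)) attr(out, "dt_s") <- dt
  out
}

# Circular FFT convolution with a kernel given as a centered array.
fft_convolve <- function(vol, kernel_centered) {
  d <- dim(vol)
  k <- array(0, d)
  kd <- dim(kernel_centered)
  if (any(kd > d)) stop("PSF larger than image")
  ctr <- (kd + 1) %/% 2
  idx <- lapply(seq_along(d), function(i)
    ((seq_len(kd[i]) - ctr[i]) %% d[i]) + 1L)
  k[as.matrix(expand.grid(idx))] <- kernel_centered
  Re(stats::fft(stats::fft(vol) * stats::fft(k), inverse = TRUE)) / length(vol)
}

#' Richardson-Lucy deconvolution with a user-supplied PSF
#'
#' Generic iterative deconvolution hook: multiplicative Richardson-Lucy
#' updates with circular FFT convolutions. The PSF is normalized to unit
#' sum internally; output is non-negative and flux-conserving.
#'
#' @param stack numeric array (2D or 3D).
#' @param psf point-spread function, same dimensionality as `stack`,
#'   non-negative, no larger than the image.
#' @param iterations iteration count (0 = identity).
#' @return Deconvolved array.
#' @export
deconvolve <- function(stack, psf, iterations = 20) {
  if (any(psf < 0)) stop("PSF must be non-negative")
  psf <- psf / sum(psf)
  if (iterations == 0) return(stack)
  est <- stack
  est[est < 0] <- 0
  psf_flip <- psf
  for (dd in seq_along(dim(psf)))
    psf_flip <- index_dim(psf_flip, rev(seq_len(dim(psf)[dd])), dd)
  for (it in seq_len(iterations)) {
    denom <- fft_convolve(est, psf)
    denom[denom < 1e-12] <- 1e-12
    est <- est * fft_convolve(stack / denom, psf_flip)
    est[est < 0] <- 0
  }
  est
}
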