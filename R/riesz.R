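#' Frequency-domain filters for single-shot DIC conversion
#'
#' A DIC microscope renders the specimen's optical-path gradient along the
#' prism's shear axis, superimposed on (inverted) absorption contrast. The
#' filters built here act on the 2D Fourier transform of such an image and
#' undo the shadow-cast appearance:
#'
#' * `ht_filter()`: directional Hilbert transform, `H(w) = -i * sgn(w . d)`
#'   with `d = (cos theta, sin theta)` the shear direction. Removes shadows
#'   but is blind to features oriented along the shear axis and its abrupt
#'   sign change creates line artifacts.
#' * `riesz1_filter()`: first-order directional Riesz transform,
#'   `H(w) = -i * (w . d) / |w|` — a smooth HT with narrower orientation
#'   selectivity.
#' * `riesz2_filter()`: second-order directional Riesz transform,
#'   `H(w) = -(w . d)^2 / |w|^2`, a real, even, sign-inverting filter that
#'   selectively passes features perpendicular to `d`.
#' * `composite_filter()`: the RT-DIC filter — first-order RT along the
#'   shear axis plus second-order RT along the orthogonal axis, times a
#'   Gaussian high-pass envelope `1 - exp(-|w|^2 / (2 s^2))` that removes DC
#'   and low-frequency shading bias.
#'
#' All filters are zero at DC, bounded by `|H| <= 1`, and numerically
#' Hermitian-symmetrized (including the Nyquist rows/columns of even-sized
#' grids) so filtering a real image yields a real image.
#'
#' @param shape integer vector `c(nx, ny)`, both at least 8.
#' @param theta shear angle in degrees, measured from the +x axis toward +y
#'   (y points down on screen); default 45.
#' @param hp_sigma high-pass scale in cycles/pixel (Nyquist = 0.5). Default
#'   `0.01` (1/50 of Nyquist).
#' @return A complex matrix of class `rtdic_filter` with attributes `kind`,
#'   `theta`, and `hp_sigma`.
#' @seealso [apply_filter()], [rtdic_convert()]
#' @examples
#' f <- composite_filter(c(64, 64))
#' Mod(f[1, 1])  # DC coefficient is zero
#' @name riesz_filters
NULL

freq_grid <- function(shape) {
  list(u = outer(fft_freq(shape[1]), rep(1, shape[2])),
       v = outer(rep(1, shape[1]), fft_freq(shape[2])))
}

# Index map w -> -w on the DFT grid.
neg_index <- function(n) c(1L, rev(seq_len(n - 1L) + 1L))

# Enforce H(-w) = Conj(H(w)) exactly (makes real input give real output,
# fixing the self-conjugate Nyquist bins of even-sized grids).
hermitianize <- function(H) {
  Hn <- Conj(H[neg_index(nrow(H)), neg_index(ncol(H)), drop = FALSE])
  (H + Hn) / 2
}

check_filter_shape <- function(shape) {
  if (length(shape) != 2 || any(shape < 8))
    stop("filter shape must be two dimensions, each >= 8")
  as.integer(shape)
}

new_filter <- function(H, kind, theta, hp_sigma = NA_real_) {
  structure(H, class = "rtdic_filter", kind = kind, theta = theta,
            hp_sigma = hp_sigma)
}

#' @rdname riesz_filters
#' @export
ht_filter <- function(shape, theta = 45) {
  shape <- check_filter_shape(shape)
  g <- freq_grid(shape)
  d <- c(cos(deg2rad(theta)), sin(deg2rad(theta)))
  wd <- g$u * d[1] + g$v * d[2]
  wd[abs(wd) < 1e-12] <- 0  # frequencies perpendicular to the shear axis
  H <- -1i * sign(wd)
  H[1, 1] <- 0
  new_filter(hermitianize(H), "ht", theta)
}

#' @rdname riesz_filters
#' @export
riesz1_filter <- function(shape, theta = 45) {
  shape <- check_filter_shape(shape)
  g <- freq_grid(shape)
  d <- c(cos(deg2rad(theta)), sin(deg2rad(theta)))
  r <- sqrt(g$u^2 + g$v^2)
  r[1, 1] <- 1
  H <- -1i * (g$u * d[1] + g$v * d[2]) / r
  H[1, 1] <- 0
  new_filter(hermitianize(H), "riesz1", theta)
}

#' @rdname riesz_filters
#' @export
riesz2_filter <- function(shape, theta = 45) {
  shape <- check_filter_shape(shape)
  g <- freq_grid(shape)
  d <- c(cos(deg2rad(theta)), sin(deg2rad(theta)))
  r2 <- g$u^2 + g$v^2
  r2[1, 1] <- 1
  H <- -(g$u * d[1] + g$v * d[2])^2 / r2
  H[1, 1] <- 0
  new_filter(hermitianize(H + 0i), "riesz2", theta)
}

#' @rdname riesz_filters
#' @export
composite_filter <- function(shape, theta = 45, hp_sigma = 0.01) {
  shape <- check_filter_shape(shape)
  stopifnot(hp_sigma > 0)
  g <- freq_grid(shape)
  r2 <- g$u^2 + g$v^2
  hp <- 1 - exp(-r2 / (2 * hp_sigma^2))
  H <- (unclass(riesz1_filter(shape, theta)) +
          unclass(riesz2_filter(shape, theta + 90))) * hp
  new_filter(hermitianize(H), "composite", theta, hp_sigma)
}

# Rebuild a filter of the same kind/parameters for a new grid shape
# (needed when the image is padded before the FFT).
filter_for_shape <- function(f, shape) {
  if (all(dim(f) == shape)) return(f)
  kind <- attr(f, "kind")
  theta <- attr(f, "theta")
  switch(kind,
         ht = ht_filter(shape, theta),
         riesz1 = riesz1_filter(shape, theta),
         riesz2 = riesz2_filter(shape, theta),
         composite = composite_filter(shape, theta, attr(f, "hp_sigma")),
         stop("cannot rebuild filter of kind ", kind))
}

#' Apply a frequency-domain filter to an image plane
#'
#' Filtering is FFT multiplication: `ifft(H * fft(plane))`. With
#' `pad = "mirror"` the plane is mirror-padded by 25% per side before the
#' FFT (and cropped afterwards) to suppress wrap-around ringing at the
#' borders; the filter is rebuilt for the padded grid.
#'
#' @param plane numeric matrix (at least 8 x 8, finite values).
#' @param f an [rtdic_filter][riesz_filters].
#' @param pad `"mirror"` (default) or `"none"`.
#' @return A real matrix of the same shape as `plane`.
#' @export
apply_filter <- function(plane, f, pad = c("mirror", "none")) {
  pad <- match.arg(pad)
  if (!all(is.finite(plane))) stop("plane contains non-finite values")
  nx <- nrow(plane); ny <- ncol(plane)
  if (pad == "mirror") {
    px <- ceiling(nx / 4); py <- ceiling(ny / 4)
    work <- mirror_pad(plane, px, py)
  } else {
    px <- py <- 0L
    work <- plane
  }
  H <- filter_for_shape(f, dim(work))
  if (!all(dim(H) == dim(work))) stop("filter shape incompatible with plane")
  out <- stats::fft(stats::fft(work) * unclass(H), inverse = TRUE) / length(work)
  resid <- max(abs(Im(out)))
  rng <- max(diff(range(Re(out))), diff(range(plane)))
  if (rng > 0 && resid > 1e-9 * rng)
    warning("imaginary residue ", signif(resid, 3), " exceeds 1e-9 of range")
  out <- Re(out)
  out[seq_len(nx) + px, seq_len(ny) + py, drop = FALSE]
}

#' Convert shadow-cast DIC images to self-luminous intensity images
#'
#' Applies the composite RT-DIC filter plane-by-plane. For 3D stacks or
#' movies (3D/4D arrays) the 2D filter is applied to every `[x, y]` plane:
#' the DIC shear lies in-plane, so the conversion is inherently 2D.
#' Optionally clips negative values to zero, which extracts the
#' fluorescence-like "self-luminous" image.
#'
#' @param x numeric matrix, 3D, or 4D array (`[x, y(, z)(, t)]`).
#' @param theta shear angle in degrees (default 45).
#' @param hp_sigma high-pass scale in cycles/pixel (default 0.01).
#' @param threshold if `TRUE`, negative output values are set to 0.
#' @param pad border handling passed to [apply_filter()].
#' @return Array of the same shape and attributes (`pitch_nm`, `dt_s`
#'   metadata is preserved when present).
#' @export
rtdic_convert <- function(x, theta = 45, hp_sigma = 0.01, threshold = TRUE,
                          pad = "mirror") {
  d <- dim(x)
  if (is.null(d) || length(d) < 2) stop("x must be a matrix or array")
  f <- composite_filter(d[1:2], theta, hp_sigma)
  out <- x
  if (length(d) == 2) {
    out[] <- apply_filter(x, f, pad)
  } else {
    planes <- prod(d[-(1:2)])
    xm <- array(x, c(d[1], d[2], planes))
    om <- xm
    for (p in seq_len(planes)) om[, , p] <- apply_filter(xm[, , p], f, pad)
    out[] <- om
  }
  if (threshold) out[out < 0] <- 0
  for (a in c("pitch_nm", "dt_s")) attr(out, a) <- attr(x, a)
  out
}
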