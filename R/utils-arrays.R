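# Internal n-dimensional array helpers shared by all modules.
#
# Arrays follow the display convention throughout the package:
# dim 1 = x (rightward on screen), dim 2 = y (downward on screen),
# dim 3 = z (away from the viewer) for volumes, last dim = time for movies.
# (x right, y down, z away) is a right-handed frame, so ordinary cross
# products carry the package's chirality sign convention.

# Subset an array along one dimension, keeping all others.
index_dim <- function(a, idx, dim) {
  nd <- length(dim(a))
  args <- rep(list(quote(expr = )), nd)
  args[[dim]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# Neighbour lookup: b[i] = a[i + k] along `dim`, with replicate (Neumann)
# or circular boundary handling.
take_shifted <- function(a, k, dim, boundary = c("replicate", "circular")) {
  boundary <- match.arg(boundary)
  n <- dim(a)[dim]
  idx <- seq_len(n) + k
  if (boundary == "circular") {
    idx <- ((idx - 1L) %% n) + 1L
  } else {
    idx <- pmin(pmax(idx, 1L), n)
  }
  index_dim(a, idx, dim)
}

# Correlation form: out[i] = sum_j k[j] * a[i + offsets[j]].
convolve_dim <- function(a, kernel, offsets, dim,
                         boundary = c("replicate", "circular")) {
  boundary <- match.arg(boundary)
  out <- array(0, dim(a))
  for (j in seq_along(kernel)) {
    if (kernel[j] == 0) next
    out <- out + kernel[j] * take_shifted(a, offsets[j], dim, boundary)
  }
  out
}

gaussian_kernel <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(list(k = 1, o = 0L))
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma))
  o <- seq.int(-radius, radius)
  k <- exp(-o^2 / (2 * sigma^2))
  list(k = k / sum(k), o = o)
}

# Derivative-of-Gaussian kernel normalized so a unit ramp maps to slope 1.
gaussian_deriv_kernel <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(list(k = c(-0.5, 0, 0.5), o = -1:1))
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma))
  o <- seq.int(-radius, radius)
  k <- o * exp(-o^2 / (2 * sigma^2))
  k <- k / sum(o * k)
  list(k = k, o = o)
}

# Separable Gaussian blur; `sigmas` recycled over the dims listed in `dims`.
gaussian_blur <- function(a, sigmas, dims = seq_along(dim(a)),
                          boundary = "replicate") {
  sigmas <- rep_len(sigmas, length(dims))
  for (i in seq_along(dims)) {
    if (sigmas[i] <= 0) next
    kr <- gaussian_kernel(sigmas[i])
    a <- convolve_dim(a, kr$k, kr$o, dims[i], boundary)
  }
  a
}

# Central difference along `dim` (replicate boundary).
central_diff <- function(a, dim, boundary = "replicate") {
  (take_shifted(a, 1L, dim, boundary) - take_shifted(a, -1L, dim, boundary)) / 2
}

# Linear interpolation of an n-d array at fractional coordinates.
# `pts` is an m x D matrix of 1-based coordinates; sampling is clamped to
# the array extent (Neumann).
interp_linear <- function(a, pts) {
  d <- dim(a)
  nd <- length(d)
  m <- nrow(pts)
  lo <- matrix(0L, m, nd)
  fr <- matrix(0, m, nd)
  for (k in seq_len(nd)) {
    x <- pmin(pmax(pts[, k], 1), d[k])
    l <- pmin(floor(x), d[k] - 1L)
    if (d[k] == 1L) l <- rep(1, m)
    lo[, k] <- as.integer(l)
    fr[, k] <- x - l
  }
  strides <- cumprod(c(1L, d[-nd]))
  out <- numeric(m)
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (ci in seq_len(nrow(corners))) {
    cc <- corners[ci, ]
    w <- rep(1, m)
    lin <- rep(1, m)
    for (k in seq_len(nd)) {
      idx <- pmin(lo[, k] + cc[k], d[k])
      lin <- lin + (idx - 1) * strides[k]
      w <- w * (if (cc[k] == 1) fr[, k] else 1 - fr[, k])
    }
    out <- out + w * a[lin]
  }
  out
}

# Mirror-pad a matrix by (px, py) pixels on each side.
mirror_pad <- function(m, px, py) {
  nx <- nrow(m); ny <- ncol(m)
  # reflect without repeating the edge sample
  reflect <- function(i, n) {
    i <- ((i - 1) %% (2 * n - 2)) + 1
    ifelse(i > n, 2 * n - i, i)
  }
  ix <- reflect(seq.int(1 - px, nx + px), nx)
  iy <- reflect(seq.int(1 - py, ny + py), ny)
  m[ix, iy, drop = FALSE]
}

# Standard DFT frequencies in cycles per sample (zero bin first).
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  f <- ifelse(k <= n %/% 2, k, k - n)
  # for even n the bin n/2 is the (self-conjugate) Nyquist bin
  if (n %% 2 == 0) f[n %/% 2 + 1L] <- n %/% 2
  f / n
}

# Subpixel translation of a plane by s = c(dx, dy) via Fourier phase ramp:
# out(x) = in(x - s) for band-limited content (circular boundary).
fourier_shift <- function(m, s) {
  fu <- fft_freq(nrow(m))
  fv <- fft_freq(ncol(m))
  ph <- exp(-2i * pi * (outer(fu * s[1], rep(1, ncol(m))) +
                          outer(rep(1, nrow(m)), fv * s[2])))
  # keep the Nyquist bins real so the output stays real
  if (nrow(m) %% 2 == 0) ph[nrow(m) %/% 2 + 1L, ] <- Re(ph[nrow(m) %/% 2 + 1L, ])
  if (ncol(m) %% 2 == 0) ph[, ncol(m) %/% 2 + 1L] <- Re(ph[, ncol(m) %/% 2 + 1L])
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / length(m)
}

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

vnorm <- function(x) sqrt(sum(x^2))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angles (degrees) to (-180, 180].
wrap_deg <- function(x) {
  w <- ((x + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}
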