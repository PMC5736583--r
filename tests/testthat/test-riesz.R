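# Non-Nyquist frequency bins of an even-sized grid (the odd-symmetric
# filters are zeroed on the self-conjugate Nyquist rows/columns to keep
# real outputs real, so analytic identities hold off those bins).
off_nyquist <- function(n) {
  m <- matrix(TRUE, n[1], n[2])
  if (n[1] %% 2 == 0) m[n[1] / 2 + 1, ] <- FALSE
  if (n[2] %% 2 == 0) m[, n[2] / 2 + 1] <- FALSE
  m[1, 1] <- FALSE
  m
}

test_that("all filters are DC-free, Hermitian, and non-amplifying", {
  shapes <- list(c(64, 64), c(48, 80), c(33, 47))
  for (sh in shapes) for (th in c(0, 45, 117)) {
    for (f in list(ht_filter(sh, th), riesz1_filter(sh, th),
                   riesz2_filter(sh, th),
                   composite_filter(sh, th, 0.01))) {
      H <- unclass(f)
      expect_equal(Mod(H[1, 1]), 0)
      neg <- function(n) c(1, rev(seq_len(n - 1) + 1))
      expect_lt(max(Mod(H - Conj(H[neg(sh[1]), neg(sh[2])]))), 1e-12)
      expect_lte(max(Mod(H)), 1 + 1e-12)
    }
  }
})

test_that("directional HT applied twice negates a zero-mean cosine along the shear axis", {
  n <- 64
  i <- seq_len(n)
  cs <- outer(i, i, function(a, b) cos(2 * pi * 4 * (a + b) / n))
  H <- ht_filter(c(n, n), 45)
  twice <- apply_filter(apply_filter(cs, H, pad = "none"), H, pad = "none")
  expect_lt(max(abs(twice + cs)), 1e-9)
  # frequencies perpendicular to the shear axis pass through as zero
  perp <- outer(i, i, function(a, b) cos(2 * pi * 4 * (a - b) / n))
  expect_lt(max(abs(apply_filter(perp, H, pad = "none"))), 1e-9)
})

test_that("first-order RT satisfies the quadrature-pair identity", {
  sh <- c(64, 48)
  ok <- off_nyquist(sh)
  H1 <- unclass(riesz1_filter(sh, 30))
  H2 <- unclass(riesz1_filter(sh, 120))
  expect_lt(max(Mod(H1[ok]^2 + H2[ok]^2 + 1)), 1e-9)
  # parallel frequencies reach |H| = 1, perpendicular ones vanish
  g <- expand.grid(u = rtdic:::fft_freq(sh[1]), v = rtdic:::fft_freq(sh[2]))
  H0 <- unclass(riesz1_filter(sh, 0))
  par <- which(g$v == 0 & g$u != 0 & abs(g$u) < 0.5)
  expect_lt(max(abs(Mod(H0[par]) - 1)), 1e-12)
  perp <- which(g$u == 0 & g$v != 0)
  expect_lt(max(Mod(H0[perp])), 1e-12)
})

test_that("second-order RT pair sums to the (negated) identity off DC", {
  sh <- c(64, 64)
  ok <- off_nyquist(sh)
  H1 <- unclass(riesz2_filter(sh, 45))
  H2 <- unclass(riesz2_filter(sh, 135))
  expect_lt(max(Mod(H1[ok] + H2[ok] + 1)), 1e-9)
})

test_that("composite filter is DC-zero and approaches the plain composite at small hp_sigma", {
  sh <- c(64, 64)
  for (s in c(0.001, 0.01, 0.1))
    expect_equal(Mod(unclass(composite_filter(sh, 45, s))[1, 1]), 0)
  tiny <- unclass(composite_filter(sh, 45, 1e-4))
  plain <- unclass(riesz1_filter(sh, 45)) + unclass(riesz2_filter(sh, 135))
  ok <- off_nyquist(sh)
  hi <- ok & (abs(outer(rtdic:::fft_freq(64), rep(1, 64))) > 0.05 |
                abs(outer(rep(1, 64), rtdic:::fft_freq(64))) > 0.05)
  expect_lt(max(Mod(tiny[hi] - plain[hi])), 1e-9)
})

test_that("filtering is linear, real-valued, and padding only affects borders", {
  set.seed(8)
  A <- matrix(rnorm(64 * 64), 64, 64)
  B <- matrix(rnorm(64 * 64), 64, 64)
  f <- composite_filter(c(64, 64))
  expect_equal(apply_filter(matrix(0, 64, 64), f), matrix(0, 64, 64))
  lin <- apply_filter(2 * A - 3 * B, f, pad = "none")
  ref <- 2 * apply_filter(A, f, pad = "none") -
    3 * apply_filter(B, f, pad = "none")
  expect_lt(max(abs(lin - ref)), 1e-10)
  # interior agreement between mirror padding and no padding on the grating
  g <- radial_grating(c(128, 128), 8)
  d <- synth_dic(g)
  rm_ <- apply_filter(d, composite_filter(c(128, 128)))
  rn <- apply_filter(d, composite_filter(c(128, 128)), pad = "none")
  interior <- 33:96
  gap <- max(abs(rm_[interior, interior] - rn[interior, interior]))
  expect_lt(gap, 0.01 * diff(range(rm_)))
})

test_that("composite restores spokes at every orientation where HT cannot", {
  n <- 256
  g <- radial_grating(c(n, n), 16, binary = TRUE)
  d <- synth_dic(g)
  rc <- apply_filter(d, composite_filter(c(n, n)))
  rh <- apply_filter(d, ht_filter(c(n, n)))
  xx <- outer(1:n - (n + 1) / 2, rep(1, n)); yy <- t(xx)
  phi <- atan2(yy, xx); rr <- sqrt(xx^2 + yy^2)
  # evaluate in the filter's operating band (|omega| ~ 0.27-0.8 rad/px,
  # where cellular features live at microscope sampling rates)
  ann <- rr >= 20 & rr <= 60
  # restored ridge contrast per spoke period: mean restored intensity on
  # the true bright spoke minus the adjacent dark gap
  sector <- floor(((phi + pi) / (2 * pi)) * 16) %% 16
  contrast <- function(r) vapply(0:15, function(s) {
    mean(r[ann & sector == s & g > 0.5]) -
      mean(r[ann & sector == s & g < 0.5])
  }, numeric(1))
  ec <- contrast(rc); eh <- contrast(rh)
  expect_gte(min(ec) / max(ec), 0.5)
  expect_lt(min(eh) / max(eh), 0.5)
})

test_that("high-pass composite output is robust to low-frequency shading bias", {
  g <- radial_grating(c(256, 256), 16)
  d <- synth_dic(g)
  xx <- outer(1:256, rep(1, 256)) / 256; yy <- t(xx)
  # smooth shading at a modest fraction of the unit dynamic range
  bias <- 0.2 * xx + 0.1 * yy + 0.2 * exp(-((xx - 0.3)^2 + (yy - 0.7)^2) / 0.4)
  f <- composite_filter(c(256, 256), 45, 0.01)
  r0 <- apply_filter(d, f)
  r1 <- apply_filter(d + bias, f)
  expect_lt(sqrt(mean((r1 - r0)^2)) / sqrt(mean(r0^2)), 0.02)
})

test_that("rtdic_convert thresholds, preserves metadata, and brightens shear-aligned dark fibers", {
  # dark 45-degree fiber in a DIC-like image (pure absorption: the
  # gradient term vanishes for features along the shear axis)
  n <- 96
  fib <- exp(-((outer(1:n, rep(1, n)) - outer(rep(1, n), 1:n))^2) / (2 * 2^2))
  dic <- -fib
  out <- rtdic_convert(dic, threshold = FALSE)
  on_fiber <- cbind(20:70, 20:70)
  off_fiber <- cbind(20:70, (20:70) + 14)
  expect_gt(mean(out[on_fiber]), 0)
  expect_gt(mean(out[on_fiber]), mean(out[off_fiber]) + 0.01)
  thr <- rtdic_convert(dic, threshold = TRUE)
  expect_gte(min(thr), 0)
  # plane-wise conversion of a stack preserves shape and attributes
  mov <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  attr(mov, "pitch_nm") <- c(100, 100); attr(mov, "dt_s") <- 2
  cv <- rtdic_convert(mov)
  expect_equal(dim(cv), dim(mov))
  expect_equal(attr(cv, "pitch_nm"), c(100, 100))
  expect_equal(cv[, , 2], rtdic_convert(mov[, , 2]), ignore_attr = TRUE)
})
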