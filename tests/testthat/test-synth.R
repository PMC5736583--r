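test_that("radial grating has the stated analytic structure", {
  g <- radial_grating(c(256, 256), 16)
  expect_true(all(g >= 0 & g <= 1))
  # on the phi = 0 axis (x > center, y = center) cos(N phi) = 1; the
  # center row pair straddles phi = 0 by half a pixel, so evaluate away
  # from the center where that half-pixel subtends a negligible angle
  expect_gt(min(g[200:250, 128] + g[200:250, 129]) / 2, 0.97)
  # even spoke count: image equals its own 180-degree rotation
  expect_lt(max(abs(g - g[256:1, 256:1])), 1e-12)
  # mean over a full annulus equals the angular mean of 0.5 (1 + cos),
  # computed independently by numeric integration over phi
  phi <- seq(0, 2 * pi, length.out = 20001)[-20001]
  oracle <- mean(0.5 * (1 + cos(16 * phi)))
  xx <- outer(1:256 - 128.5, rep(1, 256))
  yy <- t(xx)
  ann <- sqrt(xx^2 + yy^2) >= 60 & sqrt(xx^2 + yy^2) <= 90
  expect_equal(mean(g[ann]), oracle, tolerance = 0.01)
  expect_error(radial_grating(c(64, 64), 15), "even")
  expect_error(radial_grating(c(64, 64), 2), "even")
  # binary variant is the thresholded pattern
  gb <- radial_grating(c(64, 64), 8, binary = TRUE)
  expect_setequal(unique(as.vector(gb)), c(0, 1))
})

test_that("synthetic DIC rendering matches a brute-force pixel-loop oracle", {
  # constant plane: zero gradient, pure inversion
  cst <- matrix(3, 16, 16)
  expect_equal(synth_dic(cst), -cst)
  # linear ramp along the shear axis: -I plus a constant slope
  th <- 30
  d <- c(cos(th * pi / 180), sin(th * pi / 180))
  ramp <- outer(1:32, rep(1, 32)) * d[1] + outer(rep(1, 32), 1:32) * d[2]
  out <- synth_dic(ramp, theta = th)
  interior <- out[2:31, 2:31] + ramp[2:31, 2:31]
  expect_lt(max(abs(interior - 1)), 1e-10)
  # grating input vs an independent double-loop rendering
  g <- radial_grating(c(48, 48), 8)
  th <- 45
  dd <- c(cos(th * pi / 180), sin(th * pi / 180))
  oracle <- matrix(0, 48, 48)
  for (i in 1:48) for (j in 1:48) {
    ip <- min(i + 1, 48); im <- max(i - 1, 1)
    jp <- min(j + 1, 48); jm <- max(j - 1, 1)
    gx <- (g[ip, j] - g[im, j]) / 2
    gy <- (g[i, jp] - g[i, jm]) / 2
    oracle[i, j] <- -g[i, j] + dd[1] * gx + dd[2] * gy
  }
  expect_lt(max(abs(synth_dic(g, th) - oracle)), 1e-12)
  expect_error(synth_dic(matrix(c(1, NA, 1, 1), 2)), "finite")
})

test_that("helical blob ground truth matches closed forms and a finite-difference oracle", {
  # planar circle: |v| = r Omega, angular speed Omega about +z
  hb <- helical_blob_movie(r_um = 2, h_um = 0, omega = 0.05)
  spd <- sqrt(hb$truth$vx^2 + hb$truth$vy^2 + hb$truth$vz^2)
  expect_equal(spd, rep(0.1, 7), tolerance = 1e-12)
  expect_equal(hb$truth$wz, rep(0.05, 7), tolerance = 1e-12)
  expect_equal(hb$truth$wx, rep(0, 7), tolerance = 1e-12)
  # at rest every kinematic vector vanishes
  hb0 <- helical_blob_movie(omega = 0)
  kin_cols <- c("vx", "vy", "vz", "ax", "ay", "az", "jx", "jy", "jz",
                "wx", "wy", "wz")
  expect_true(all(abs(as.matrix(hb0$truth[kin_cols])) < 1e-15))
  # full helix: truth equals dense finite differencing of the path
  hb2 <- helical_blob_movie(r_um = 2, h_um = 1, omega = 0.05, dt_s = 4)
  p <- function(t) {
    ph <- 0.05 * t
    c(2 * cos(ph), 2 * sin(ph), 1 * 0.05 * (t - 12) / (2 * pi))
  }
  h <- 4 / 100
  for (k in c(2, 4, 6)) {
    t0 <- hb2$truth$t[k]
    v_fd <- (p(t0 + h) - p(t0 - h)) / (2 * h)
    a_fd <- (p(t0 + h) - 2 * p(t0) + p(t0 - h)) / h^2
    v_tr <- as.numeric(hb2$truth[k, c("vx", "vy", "vz")])
    a_tr <- as.numeric(hb2$truth[k, c("ax", "ay", "az")])
    expect_lt(max(abs(v_fd - v_tr)) / max(abs(v_tr)), 1e-3)
    expect_lt(max(abs(a_fd - a_tr)) / max(abs(a_tr)), 1e-3)
  }
  # blob escaping the volume is rejected
  expect_error(helical_blob_movie(r_um = 5), "margin|volume")
})

test_that("filopodium phantom exposes construction-true axial quantities with parity", {
  fp <- filopodium_phantom(retract_um_s = 0.02, spin_rad_s = 0.03)
  expect_equal(fp$truth$axial_velocity_um_s, -0.02)
  expect_equal(fp$truth$axial_angular_velocity_rad_s, 0.03)
  fp0 <- filopodium_phantom(spin_rad_s = 0)
  expect_equal(fp0$truth$axial_angular_velocity_rad_s, 0)
  # mirroring about x flips the chirality sign and nothing else
  fpm <- filopodium_phantom(retract_um_s = 0.02, spin_rad_s = 0.03,
                            mirror = TRUE)
  expect_equal(fpm$truth$axial_angular_velocity_rad_s, -0.03)
  expect_equal(fpm$truth$axial_velocity_um_s, -0.02)
  nx <- dim(fp$movie)[1]
  expect_equal(fpm$movie[nx:1, , , ], fp$movie[, , , ],
               ignore_attr = TRUE)
  expect_error(filopodium_phantom(n_frames = 50, retract_um_s = 0.05),
               "underflow")
  expect_error(filopodium_phantom(radius_um = 0.3), "radius")
})

test_that("2D walkers follow the prescribed heading dynamics", {
  # no bias, no noise: straight lines
  w0 <- walker_movie_2d(n = 3, n_frames = 20, omega0_deg_min = 0,
                        noise_deg = 0, render = FALSE, seed = 5)
  cs0 <- chirality_stats(w0$truth, 30, 2.58, min_step_px = 0)
  expect_lt(max(abs(cs0$steps$cum_deg)), 1e-9)
  # pure bias: a circle of radius speed / |omega0|
  wc <- walker_movie_2d(n = 1, n_frames = 60, omega0_deg_min = 0.8,
                        noise_deg = 0, shape = c(700, 700),
                        render = FALSE, seed = 5)
  csc <- chirality_stats(wc$truth, 30, 2.58, min_step_px = 0)
  r_expect_mm <- (8 / (0.8 * pi / 180)) / 1000
  expect_equal(csc$per_track$curvature_rad_mm, 1 / r_expect_mm,
               tolerance = 0.02)
  # noisy ensemble: empirical mean heading increment recovers the bias
  wn <- walker_movie_2d(n = 50, n_frames = 120, render = FALSE, seed = 9)
  tr <- wn$truth
  dphi <- unlist(tapply(tr$heading_deg, tr$id, function(h) {
    d <- diff(h); ((d + 180) %% 360) - 180
  }))
  rate <- dphi / 0.5  # deg per min at dt = 30 s
  se <- sd(rate) / sqrt(length(rate))
  expect_lt(abs(mean(rate) - 0.8), 3 * se)
})

test_that("generators are deterministic under a fixed seed", {
  a <- walker_movie_2d(n = 5, shape = c(64, 64), n_frames = 6, seed = 11)
  b <- walker_movie_2d(n = 5, shape = c(64, 64), n_frames = 6, seed = 11)
  expect_identical(a$movie, b$movie)
  expect_identical(a$truth, b$truth)
  h1 <- helical_blob_movie(noise_sd = 0.01, seed = 4)
  h2 <- helical_blob_movie(noise_sd = 0.01, seed = 4)
  expect_identical(h1$movie, h2$movie)
  # generators do not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(walker_movie_2d(n = 2, n_frames = 3,
                                         render = FALSE, seed = 99))
  r2 <- runif(1)
  expect_identical(r1, r2)
})
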