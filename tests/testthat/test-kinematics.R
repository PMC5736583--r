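test_that("five-point stencils differentiate cubic paths exactly", {
  p <- function(t) c(0.1 + 0.2 * t - 0.05 * t^2 + 0.03 * t^3,
                     1 - 0.1 * t + 0.02 * t^3,
                     0.5 * t + 0.01 * t^2)
  # analytic derivatives (the oracle)
  v_an <- function(t) c(0.2 - 0.1 * t + 0.09 * t^2, -0.1 + 0.06 * t^2,
                        0.5 + 0.02 * t)
  a_an <- function(t) c(-0.1 + 0.18 * t, 0.12 * t, 0.02)
  j_an <- function(t) c(0.18, 0.12, 0)
  for (dt in c(0.3, 1, 2.5)) for (t0 in c(0, 1.7)) {
    fs <- flowset_from_path(p, t0, dt)
    kin <- derive_kinematics(fs, dt, 1, tau_v = 0)
    got <- function(fld) vapply(1:3, function(c2) fld[[c2]][1, 1, 1],
                                numeric(1))
    expect_equal(got(kin$v), v_an(t0), tolerance = 1e-10)
    expect_equal(got(kin$a), a_an(t0), tolerance = 1e-10)
    expect_equal(got(kin$j), j_an(t0), tolerance = 1e-10)
  }
})

test_that("uniform translation yields no acceleration, jerk, or rotation", {
  p <- function(t) c(0.4, -0.2, 0.1) * t
  fs <- flowset_from_path(p, 1, 0.5)
  kin <- derive_kinematics(fs, 0.5, 1, tau_v = 0)
  expect_lt(max(abs(kin$a[[1]]), abs(kin$a[[2]]), abs(kin$a[[3]])), 1e-12)
  expect_lt(max(abs(kin$j[[1]]))
            + max(abs(kin$j[[2]])) + max(abs(kin$j[[3]])), 1e-11)
  expect_false(any(kin$frenet_ok))
})

test_that("circular motion gives the Frenet angular velocity with chirality sign", {
  r <- 2; om <- 0.05
  p <- function(t) c(r * cos(om * t), r * sin(om * t), 0)
  fs <- flowset_from_path(p, 10, 1)
  kin <- derive_kinematics(fs, 1, 1, tau_v = 0)
  # rotation from +x toward +y is right-screw about +z (clockwise on
  # screen with y down): w_z must be positive, close to Omega
  expect_equal(kin$w[[3]][2, 2, 2], om, tolerance = 0.01)
  expect_lt(abs(kin$w[[1]][2, 2, 2]) + abs(kin$w[[2]][2, 2, 2]), 1e-4)
  # w is perpendicular to v
  wv <- kin$w[[1]] * kin$v[[1]] + kin$w[[2]] * kin$v[[2]] +
    kin$w[[3]] * kin$v[[3]]
  expect_lt(max(abs(wv)), 1e-6)
  # Frenet triad orthonormality
  dots <- c(kin$T[[1]] * kin$N[[1]] + kin$T[[2]] * kin$N[[2]] +
              kin$T[[3]] * kin$N[[3]],
            kin$T[[1]] * kin$B[[1]] + kin$T[[2]] * kin$B[[2]] +
              kin$T[[3]] * kin$B[[3]],
            kin$N[[1]] * kin$B[[1]] + kin$N[[2]] * kin$B[[2]] +
              kin$N[[3]] * kin$B[[3]])
  expect_lt(max(abs(dots)), 1e-6)
  # mirror parity: negating y flips the sign of w_z
  pm <- function(t) { q <- p(t); c(q[1], -q[2], q[3]) }
  km <- derive_kinematics(flowset_from_path(pm, 10, 1), 1, 1, tau_v = 0)
  expect_equal(km$w[[3]][2, 2, 2], -kin$w[[3]][2, 2, 2], tolerance = 1e-9)
})

test_that("kinematic quantities scale correctly with dt and pitch", {
  p <- function(t) c(0.3 * t + 0.02 * t^2, -0.1 * t, 0.05 * t^3)
  fs <- flowset_from_path(p, 2, 1)
  k1 <- derive_kinematics(fs, 1, 1, tau_v = 0)
  k2 <- derive_kinematics(fs, 0.5, 1, tau_v = 0)
  expect_equal(k2$v[[1]][1, 1, 1], 2 * k1$v[[1]][1, 1, 1])
  expect_equal(k2$a[[1]][1, 1, 1], 4 * k1$a[[1]][1, 1, 1])
  expect_equal(k2$j[[3]][1, 1, 1], 8 * k1$j[[3]][1, 1, 1])
  k3 <- derive_kinematics(fs, 1, 2, tau_v = 0)
  expect_equal(k3$v[[1]][1, 1, 1], 2 * k1$v[[1]][1, 1, 1])
})

test_that("chordal and orbital projections behave on straight and rotating paths", {
  # straight filopodium retracting along its axis: chordal axis equals
  # the local (fiber) axis
  n <- 9; dt <- 2
  ax <- c(0, 0, 1)
  path <- t(vapply(1:n, function(k) c(5, 5, 10 - 0.02 * dt * (k - 1)),
                   numeric(3)))
  base <- c(5, 5, 2)
  co <- chordal_orbital_axes(path, base, ax, dt)
  expect_equal(co$chordal_velocity, rep(-0.02, nrow(co)), tolerance = 1e-9)
  expect_equal(co$orbital_velocity, co$chordal_velocity, tolerance = 1e-9)
  # rigid rotation about the base: no chordal extension, pure spin
  om <- 0.1
  path2 <- t(vapply(1:n, function(k) {
    th <- om * dt * (k - 1)
    base + c(3 * cos(th), 3 * sin(th), 4)
  }, numeric(3)))
  co2 <- chordal_orbital_axes(path2, base, ax, dt)
  expect_lt(max(abs(co2$chordal_velocity)), 1e-6)
  expect_equal(co2$orbital_angular_velocity, rep(om, nrow(co2)),
               tolerance = 0.01)
  # a point sitting on the base has no chordal axis
  path3 <- matrix(rep(base, n), n, 3, byrow = TRUE)
  co3 <- chordal_orbital_axes(path3, base, ax, dt)
  expect_true(all(is.na(co3$chordal_velocity)))
})

test_that("radial projections detect outward motion and right-screw tip rotation", {
  sh <- c(20, 20, 20)
  ctr <- (sh + 1) / 2
  co <- as.matrix(expand.grid(lapply(sh, seq_len)))
  rel <- sweep(co, 2, ctr, `-`)
  rn <- sqrt(rowSums(rel^2))
  vol <- array(exp(-(rn - 6)^2 / 4), sh)
  mkf <- function(vfun) {
    arr <- array(0, c(sh, 3))
    for (c2 in 1:3) arr[, , , c2] <- array(vfun(c2), sh)
    arr
  }
  # radially exploding field: v = 0.1 * r_hat
  rhat <- rel / pmax(rn, 1e-9)
  explode <- structure(list(
    sfp = mkf(function(c2) 0.1 * rhat[, c2]),
    sfm = mkf(function(c2) -0.1 * rhat[, c2]),
    dfp = mkf(function(c2) 0.2 * rhat[, c2]),
    dfm = mkf(function(c2) -0.2 * rhat[, c2]),
    center = vol), class = "rtdic_flowset")
  kin <- derive_kinematics(explode, 1, 1, tau_v = 0, tau_i = 0.3)
  rp <- radial_axis_projection(kin)
  expect_equal(rp$centroid, ctr, tolerance = 0.1)
  expect_gt(mean(rp$radial_velocity, na.rm = TRUE), 0.05)
  # rigid rotation about +z: radial angular velocity positive
  # (right-screw about the outward axis on the +z side is mixed; use the
  # angular velocity vector directly: w = +z everywhere)
  omega <- 0.1
  spin_d <- function(k) {
    th <- omega * k
    dxy <- cbind(rel[, 1] * cos(th) - rel[, 2] * sin(th) - rel[, 1],
                 rel[, 1] * sin(th) + rel[, 2] * cos(th) - rel[, 2])
    cbind(dxy, 0)
  }
  spin <- structure(list(
    sfp = mkf(function(c2) spin_d(1)[, c2]),
    sfm = mkf(function(c2) spin_d(-1)[, c2]),
    dfp = mkf(function(c2) spin_d(2)[, c2]),
    dfm = mkf(function(c2) spin_d(-2)[, c2]),
    center = vol), class = "rtdic_flowset")
  kin2 <- derive_kinematics(spin, 1, 1, tau_v = 0, tau_i = 0.3)
  # upper hemisphere voxels (z > center): outward axis has +z component,
  # so right-screw rotation about +z projects positively there
  up <- array(rep(co[, 3] > ctr[3] + 2, 1), sh)
  rp2 <- radial_axis_projection(kin2)
  vals <- rp2$radial_angular_velocity[up & !is.na(rp2$radial_angular_velocity)]
  expect_gt(mean(vals), 0)
  expect_error(radial_axis_projection(kin2, volume = array(0, sh)),
               "zero total intensity")
})

test_that("pixel-wise 2D motility recovers circle curvature with clockwise sign", {
  # blob gliding clockwise (display convention) on a circle of R = 250 um
  pitch <- 2.58; R_px <- 250 / pitch
  n <- 72
  cx <- 36; cy <- 36 + R_px   # circle center below the arena view
  th0 <- -pi / 2              # blob at top of circle, moving +x
  step <- 6                   # px per frame along the arc
  pos <- t(vapply(-2:2, function(k) {
    th <- th0 + step * k / R_px
    c(cx + R_px * cos(th), cy + R_px * sin(th))
  }, numeric(2)))
  mov <- array(0, c(n, n, 5))
  for (k in 1:5)
    mov[, , k] <- outer(exp(-(1:n - pos[k, 1])^2 / (2 * 9)),
                        exp(-(1:n - pos[k, 2])^2 / (2 * 9)))
  attr(mov, "pitch_nm") <- c(pitch, pitch) * 1000
  attr(mov, "dt_s") <- 30
  res <- pixelwise_2d_motility(mov)
  fr <- res$frames[[1]]
  m <- fr$motile & mov[, , 3] >= 0.5 * max(mov[, , 3])
  curv_mm <- mean(fr$curvature[m], na.rm = TRUE) * 1000  # rad/um -> rad/mm
  expect_equal(curv_mm, 4, tolerance = 0.1 * 4)
  expect_gt(mean(fr$angular_velocity[m], na.rm = TRUE), 0)
})

test_that("filopodium phantom recovery: retraction speed and right-screw spin", {
  fp <- filopodium_phantom()   # retraction 0.02 um/s, spin +0.03 rad/s
  fs <- five_frame_flowset(fp$movie[, , , 3:7])
  kin <- derive_kinematics(fs, 10, 0.25)
  tf <- certainties(compute_tensor(fp$movie[, , , 5], 1, 3))
  dirf <- orient_to_tip(tf, fp$truth$base_vox)
  pr <- local_axis_projection(kin, dirf)
  expect_equal(mean(pr$axial_velocity, na.rm = TRUE), -0.02,
               tolerance = 0.30)
  expect_gt(mean(pr$axial_angular_velocity, na.rm = TRUE), 0)
  # static phantom: both projections vanish
  fp0 <- filopodium_phantom(retract_um_s = 0, spin_rad_s = 0,
                            texture_amp = 0.3)
  fs0 <- five_frame_flowset(fp0$movie[, , , 3:7], n_iter = 50)
  kin0 <- derive_kinematics(fs0, 10, 0.25)
  pr0 <- local_axis_projection(kin0, dirf)
  expect_lt(abs(mean(pr0$axial_velocity, na.rm = TRUE)), 1e-6)
  expect_false(any(kin0$motile))
})

test_that("pixel-wise angular velocity of biased walkers brackets the generator bias", {
  wm <- walker_movie_2d(n = 30, shape = c(288, 288), n_frames = 5,
                        spawn = "grid", seed = 71)
  res <- pixelwise_2d_motility(wm$movie)
  fr <- res$frames[[1]]
  av_deg_min <- fr$angular_velocity * 180 / pi * 60
  # per-walker means: assign each motile pixel to its nearest walker
  tru <- wm$truth[wm$truth$frame == 3, ]
  idx <- which(fr$motile, arr.ind = TRUE)
  near <- apply(idx, 1, function(p)
    which.min((tru$x_px - p[1])^2 + (tru$y_px - p[2])^2))
  per_walker <- tapply(av_deg_min[fr$motile], near, mean, na.rm = TRUE)
  est <- mean(per_walker)
  sem <- sd(per_walker) / sqrt(length(per_walker))
  expect_lt(abs(est - 0.8), 2 * sem)
})
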