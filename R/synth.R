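#' Synthetic phantoms with analytic ground truth
#'
#' Every downstream stage of the pipeline is validated against phantoms
#' whose kinematics are known in closed form: a radial grating and its
#' synthetic DIC rendering (filter validation), a Gaussian blob on a 3D
#' helix (flow + kinematics), a retracting/spinning cylinder emulating a
#' filopodium (axial projections), and 2D random walkers with a constant
#' clockwise angular-velocity bias (pixel-wise motility and tracking).
#'
#' Coordinates follow the display convention (x right, y down, z away from
#' the viewer; a right-handed frame). Positive angular quantities are
#' clockwise on screen / right-screw about the reference axis.
#'
#' @name synthetic_phantoms
NULL

#' Radial grating test pattern
#'
#' Intensity `0.5 * (1 + cos(N * phi))` about the image center, where `phi`
#' is the polar angle: `N` bright spokes covering every orientation, the
#' standard target for orientation-coverage tests of DIC restoration
#' filters.
#'
#' @param shape `c(nx, ny)` in pixels.
#' @param n_spokes even spoke count `N >= 4` (an odd count would break the
#'   180-degree rotational symmetry that DIC restoration assumes).
#' @param binary if `TRUE`, threshold the pattern at 0.5 to a black/white
#'   star target (the high-contrast variant used for restoration-overlap
#'   scoring); default `FALSE` returns the smooth cosine pattern.
#' @return Matrix with values in `[0, 1]`.
#' @export
radial_grating <- function(shape = c(512, 512), n_spokes = 16,
                           binary = FALSE) {
  if (n_spokes %% 2 != 0 || n_spokes < 4)
    stop("n_spokes must be even and >= 4")
  cx <- (shape[1] + 1) / 2
  cy <- (shape[2] + 1) / 2
  xx <- outer(seq_len(shape[1]) - cx, rep(1, shape[2]))
  yy <- outer(rep(1, shape[1]), seq_len(shape[2]) - cy)
  phi <- atan2(yy, xx)
  g <- 0.5 * (1 + cos(n_spokes * phi))
  if (binary) g <- (g > 0.5) * 1.0
  g
}

#' Synthesize a DIC image from a ground-truth intensity image
#'
#' Emulates the shadow-cast DIC appearance as the sum of the inverted image
#' (absorption term) and the directional gradient along the shear axis
#' (phase-gradient term): `-I + dI/dd`, `d = (cos theta, sin theta)`,
#' gradient by central differences.
#'
#' @param ground_truth numeric matrix of finite values.
#' @param theta shear angle in degrees (default 45).
#' @return Matrix of the same shape.
#' @export
synth_dic <- function(ground_truth, theta = 45) {
  if (!all(is.finite(ground_truth))) stop("ground truth must be finite")
  d <- c(cos(deg2rad(theta)), sin(deg2rad(theta)))
  gx <- central_diff(ground_truth, 1)
  gy <- central_diff(ground_truth, 2)
  -ground_truth + d[1] * gx + d[2] * gy
}

# Rotation taking the +z axis onto unit vector `axis`.
rotation_to_axis <- function(axis) {
  a <- axis / vnorm(axis)
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  c2 <- sum(z * a)
  if (vnorm(v) < 1e-12) {
    if (c2 > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 deg about x
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c2)
}

render_blob_movie <- function(path_vox, shape, sigma_vox, noise_sd = 0,
                              seed = NULL) {
  nt <- nrow(path_vox)
  mov <- array(0, c(shape, nt))
  xs <- seq_len(shape[1]); ys <- seq_len(shape[2]); zs <- seq_len(shape[3])
  for (t in seq_len(nt)) {
    p <- path_vox[t, ]
    gx <- exp(-(xs - p[1])^2 / (2 * sigma_vox^2))
    gy <- exp(-(ys - p[2])^2 / (2 * sigma_vox^2))
    gz <- exp(-(zs - p[3])^2 / (2 * sigma_vox^2))
    mov[, , , t] <- outer(outer(gx, gy), gz)
  }
  if (noise_sd > 0) mov <- mov + with_seed(seed, array(
    stats::rnorm(length(mov), sd = noise_sd), dim(mov)))
  mov
}

#' Gaussian blob moving on a 3D helix
#'
#' Renders an isotropic Gaussian blob whose center follows
#' `p(t) = c + R (r cos(W t), r sin(W t), h W t / (2 pi))`, with `R`
#' rotating the helix axis from +z onto `axis`. Returns the movie and the
#' closed-form kinematic ground truth (position, velocity, acceleration,
#' jerk, angular velocity) at every frame time.
#'
#' With `h = 0` the motion is a planar circle: speed `r * W`, angular speed
#' exactly `W`. With `W = 0` the blob is at rest and all kinematic vectors
#' vanish.
#'
#' @param shape volume shape in voxels, `c(nx, ny, nz)`.
#' @param pitch_um isotropic voxel pitch (micrometers).
#' @param dt_s frame interval (seconds).
#' @param n_frames number of frames, at least 7 (five-frame kinematics
#'   needs two frames of margin on each side).
#' @param r_um helix radius (micrometers).
#' @param h_um axial advance per turn (micrometers).
#' @param omega angular rate `W` (rad/s); positive = x toward y (right-screw
#'   about the axis).
#' @param axis helix axis direction (default +z).
#' @param sigma_um blob standard deviation (micrometers).
#' @param phase0 starting phase (radians).
#' @param noise_sd additive Gaussian noise s.d. (default 0, off).
#' @param seed RNG seed for the noise.
#' @return List with `movie` (4D array `[x, y, z, t]`, attributes
#'   `pitch_nm`, `dt_s`) and `truth` (data.frame of per-frame kinematics in
#'   micrometers and seconds).
#' @export
helical_blob_movie <- function(shape = c(40, 40, 40), pitch_um = 0.25,
                               dt_s = 2, n_frames = 7, r_um = 2, h_um = 0,
                               omega = 0.05, axis = c(0, 0, 1),
                               sigma_um = 0.75, phase0 = 0,
                               noise_sd = 0, seed = NULL) {
  stopifnot(pitch_um > 0, dt_s > 0, r_um >= 0, sigma_um > 0)
  if (n_frames < 7) stop("need at least 7 frames")
  R <- rotation_to_axis(axis)
  tt <- (seq_len(n_frames) - 1) * dt_s
  # centered so the helix midpoint sits at the volume center
  t_mid <- mean(range(tt))
  ph <- phase0 + omega * tt
  base <- cbind(r_um * cos(ph), r_um * sin(ph),
                h_um * omega * (tt - t_mid) / (2 * pi))
  pos <- base %*% t(R)
  vel <- cbind(-r_um * omega * sin(ph), r_um * omega * cos(ph),
               rep(h_um * omega / (2 * pi), n_frames)) %*% t(R)
  acc <- cbind(-r_um * omega^2 * cos(ph), -r_um * omega^2 * sin(ph),
               rep(0, n_frames)) %*% t(R)
  jrk <- cbind(r_um * omega^3 * sin(ph), -r_um * omega^3 * cos(ph),
               rep(0, n_frames)) %*% t(R)
  angvel <- t(vapply(seq_len(n_frames), function(i) {
    v <- vel[i, ]; a <- acc[i, ]
    if (vnorm(v) < 1e-300) return(c(0, 0, 0))
    cross3(v, a) / sum(v^2)
  }, numeric(3)))
  center_vox <- (dim3(shape) + 1) / 2
  path_vox <- sweep(pos / pitch_um, 2, center_vox, `+`)
  sig_vox <- sigma_um / pitch_um
  margin <- 3 * sig_vox
  if (any(path_vox < 1 + margin) ||
      any(sweep(path_vox, 2, shape, `-`) > -margin))
    stop("blob leaves the volume (needs a 3*sigma margin)")
  mov <- render_blob_movie(path_vox, shape, sig_vox, noise_sd, seed)
  attr(mov, "pitch_nm") <- rep(pitch_um * 1000, 3)
  attr(mov, "dt_s") <- dt_s
  truth <- data.frame(frame = seq_len(n_frames), t = tt,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      vx = vel[, 1], vy = vel[, 2], vz = vel[, 3],
                      ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                      jx = jrk[, 1], jy = jrk[, 2], jz = jrk[, 3],
                      wx = angvel[, 1], wy = angvel[, 2], wz = angvel[, 3])
  list(movie = mov, truth = truth)
}

dim3 <- function(shape) as.numeric(shape)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Retracting, axially spinning cylinder (filopodium phantom)
#'
#' A bright soft-edged cylinder anchored at a base point along `+z`, whose
#' length shrinks at `retract_um_s` while its material moves with the
#' retraction: an axial sinusoidal intensity texture advects toward the
#' base at the retraction speed (emulating retrograde flow), and a surface
#' texture bump revolves about the axis at `spin_rad_s`. Ground truth:
#' signed axial velocity `-retract_um_s` (negative = retraction toward the
#' base) and signed axial angular velocity `+spin_rad_s` (positive =
#' right-screw about the base-to-tip axis).
#'
#' @param shape volume shape in voxels.
#' @param pitch_um voxel pitch (micrometers).
#' @param dt_s frame interval (seconds).
#' @param n_frames frame count (>= 7).
#' @param length_um initial cylinder length.
#' @param radius_um cylinder radius (>= 2 voxels).
#' @param retract_um_s retraction speed (positive number; the tip moves at
#'   `-retract_um_s` along the axis).
#' @param spin_rad_s axial spin rate (rad/s, right-screw positive).
#' @param texture_amp amplitude of the advected axial intensity texture
#'   (fraction of the cylinder intensity).
#' @param texture_wavelength_um wavelength of the axial texture.
#' @param mirror if `TRUE`, the rendered volume is mirrored about the x
#'   plane (chirality flips: ground-truth spin sign is negated).
#' @return List with `movie` (4D array), `truth` (axial velocity and axial
#'   angular velocity, plus the base point and axis), and rendering
#'   parameters.
#' @export
filopodium_phantom <- function(shape = c(32, 32, 48), pitch_um = 0.25,
                               dt_s = 10, n_frames = 9, length_um = 8,
                               radius_um = 0.6, retract_um_s = 0.02,
                               spin_rad_s = 0.03, texture_amp = 0.4,
                               texture_wavelength_um = 2, mirror = FALSE) {
  stopifnot(n_frames >= 7)
  if (radius_um / pitch_um < 2) stop("cylinder radius must be >= 2 voxels")
  tt <- (seq_len(n_frames) - 1) * dt_s
  len_t <- length_um - retract_um_s * tt
  if (any(len_t <= 1)) stop("cylinder length underflows before movie ends")
  base_vox <- c((shape[1] + 1) / 2, (shape[2] + 1) / 2, 4)
  r_vox <- radius_um / pitch_um
  xs <- seq_len(shape[1]); ys <- seq_len(shape[2]); zs <- seq_len(shape[3])
  rad2 <- outer((xs - base_vox[1])^2, (ys - base_vox[2])^2, `+`)
  radial <- exp(-rad2 / (2 * (r_vox / 1.5)^2))
  lam_vox <- texture_wavelength_um / pitch_um
  mov <- array(0, c(shape, n_frames))
  for (k in seq_len(n_frames)) {
    tip_z <- base_vox[3] + len_t[k] / pitch_um
    # material coordinate advected toward the base at the retraction speed
    z_mat <- zs + retract_um_s * tt[k] / pitch_um
    axial <- 1 / (1 + exp(4 * (zs - tip_z))) *
      1 / (1 + exp(-4 * (zs - base_vox[3] + 1))) *
      (1 + texture_amp * sin(2 * pi * z_mat / lam_vox))
    vol <- outer(radial, axial)
    # surface texture bump revolving about the axis (and retracting)
    phi <- spin_rad_s * tt[k]
    bx <- base_vox[1] + r_vox * cos(phi)
    by <- base_vox[2] + r_vox * sin(phi)
    bz <- base_vox[3] + 0.6 * len_t[k] / pitch_um
    gb <- outer(outer(exp(-(xs - bx)^2 / (2 * (r_vox / 1.5)^2)),
                      exp(-(ys - by)^2 / (2 * (r_vox / 1.5)^2))),
                exp(-(zs - bz)^2 / (2 * (r_vox / 1.5)^2)))
    mov[, , , k] <- vol + 0.8 * gb
  }
  truth_spin <- spin_rad_s
  if (mirror) {
    mov <- mov[rev(seq_len(shape[1])), , , , drop = FALSE]
    base_vox[1] <- shape[1] + 1 - base_vox[1]
    truth_spin <- -spin_rad_s
  }
  attr(mov, "pitch_nm") <- rep(pitch_um * 1000, 3)
  attr(mov, "dt_s") <- dt_s
  list(movie = mov,
       truth = list(axial_velocity_um_s = -retract_um_s,
                    axial_angular_velocity_rad_s = truth_spin,
                    base_vox = base_vox, axis = c(0, 0, 1)),
       params = list(pitch_um = pitch_um, dt_s = dt_s,
                     radius_um = radius_um, length_um = length_um))
}

#' 2D random walkers with a clockwise heading bias
#'
#' `n` walkers advance at constant speed while their headings evolve as
#' `phi(t + dt) = phi(t) + omega0 * dt + noise`, with `omega0 > 0` a
#' clockwise (on-screen) bias and per-step Gaussian heading noise of
#' standard deviation `noise_deg * sqrt(dt in minutes)`. Walkers reaching
#' the arena border are reflected and the step flagged. Cells are rendered
#' as Gaussian blobs; set `dic = TRUE` to pass each frame through
#' [synth_dic()] for DIC-like contrast.
#'
#' With `omega0 = 0` and zero noise the trajectories are straight; with
#' noise 0 and `omega0 != 0` each trajectory is a circle of radius
#' `speed / |omega0|` (omega0 in rad per time unit).
#'
#' @param n walker count.
#' @param shape arena shape in pixels.
#' @param pitch_um pixel pitch (micrometers); default 2.58 as in low-density
#'   amoeba tracking.
#' @param dt_s frame interval (seconds); default 30.
#' @param n_frames frame count.
#' @param speed_um_min walking speed (micrometers/minute).
#' @param omega0_deg_min angular-velocity bias (degrees/minute, clockwise
#'   positive); default +0.8.
#' @param noise_deg heading noise s.d. in degrees per sqrt-minute.
#' @param blob_sigma_px rendered blob s.d. (pixels).
#' @param dic render DIC-like contrast via [synth_dic()].
#' @param render if `FALSE`, skip rendering and return ground truth only.
#' @param spawn `"uniform"` (default; random positions in the central
#'   half of the arena) or `"grid"` (jittered grid with maximal spacing,
#'   for tracking phantoms).
#' @param cell_confine with `spawn = "grid"`: confine each walker to its
#'   own grid cell by reflection, guaranteeing non-interacting walkers
#'   (reflected steps are flagged and excluded from heading statistics).
#' @param seed RNG seed (fixed seed gives byte-identical output).
#' @return List with `movie` (array `[x, y, t]` or `NULL`), `truth`
#'   (data.frame: id, frame, t_s, x_um, y_um, x_px, y_px, heading_deg,
#'   reflected), and the generator parameters.
#' @export
walker_movie_2d <- function(n = 50, shape = c(256, 256), pitch_um = 2.58,
                            dt_s = 30, n_frames = 60, speed_um_min = 8,
                            omega0_deg_min = 0.8, noise_deg = 10,
                            blob_sigma_px = 2, dic = FALSE, render = TRUE,
                            spawn = c("uniform", "grid"),
                            cell_confine = FALSE, seed = 1) {
  stopifnot(n >= 1, n_frames >= 2)
  spawn <- match.arg(spawn)
  if (cell_confine && spawn != "grid")
    stop("cell_confine requires spawn = 'grid'")
  dt_min <- dt_s / 60
  arena_um <- shape * pitch_um
  margin_um <- 4 * blob_sigma_px * pitch_um
  # per-walker reflective bounds; default the shared arena
  xlo <- rep(margin_um, n); xhi <- rep(arena_um[1] - margin_um, n)
  ylo <- rep(margin_um, n); yhi <- rep(arena_um[2] - margin_um, n)
  truth <- with_seed(seed, {
    if (spawn == "grid") {
      ncol_g <- ceiling(sqrt(n))
      nrow_g <- ceiling(n / ncol_g)
      ex <- seq(0, arena_um[1], length.out = ncol_g + 1)
      ey <- seq(0, arena_um[2], length.out = nrow_g + 1)
      cells <- expand.grid(ix = seq_len(ncol_g), iy = seq_len(nrow_g))
      cells <- cells[seq_len(n), ]
      cxlo <- ex[cells$ix] + margin_um; cxhi <- ex[cells$ix + 1] - margin_um
      cylo <- ey[cells$iy] + margin_um; cyhi <- ey[cells$iy + 1] - margin_um
      x <- stats::runif(n, cxlo + (cxhi - cxlo) / 3, cxhi - (cxhi - cxlo) / 3)
      y <- stats::runif(n, cylo + (cyhi - cylo) / 3, cyhi - (cyhi - cylo) / 3)
      if (cell_confine) {
        xlo <- cxlo; xhi <- cxhi; ylo <- cylo; yhi <- cyhi
      }
    } else {
      # spawn in the central half so short movies rarely reach the border
      x <- stats::runif(n, arena_um[1] / 4, arena_um[1] * 3 / 4)
      y <- stats::runif(n, arena_um[2] / 4, arena_um[2] * 3 / 4)
    }
    phi <- stats::runif(n, -180, 180)
    X <- Y <- P <- matrix(0, n, n_frames)
    RF <- matrix(FALSE, n, n_frames)
    X[, 1] <- x; Y[, 1] <- y; P[, 1] <- phi
    for (k in seq_len(n_frames)[-1]) {
      refl <- rep(FALSE, n)
      phi <- phi + omega0_deg_min * dt_min +
        stats::rnorm(n, sd = noise_deg * sqrt(dt_min))
      step <- speed_um_min * dt_min
      x <- x + step * cos(deg2rad(phi))
      y <- y + step * sin(deg2rad(phi))
      # reflect at (per-walker) borders, flagging the walker for this frame
      bx <- x < xlo | x > xhi
      if (any(bx)) {
        x[bx] <- pmin(pmax(x[bx], xlo[bx]), xhi[bx])
        phi[bx] <- wrap_deg(180 - phi[bx])
        refl[bx] <- TRUE
      }
      by <- y < ylo | y > yhi
      if (any(by)) {
        y[by] <- pmin(pmax(y[by], ylo[by]), yhi[by])
        phi[by] <- wrap_deg(-phi[by])
        refl[by] <- TRUE
      }
      X[, k] <- x; Y[, k] <- y; P[, k] <- phi; RF[, k] <- refl
    }
    data.frame(id = rep(seq_len(n), n_frames),
               frame = rep(seq_len(n_frames), each = n),
               t_s = rep((seq_len(n_frames) - 1) * dt_s, each = n),
               x_um = as.vector(X), y_um = as.vector(Y),
               x_px = as.vector(X) / pitch_um,
               y_px = as.vector(Y) / pitch_um,
               heading_deg = wrap_deg(as.vector(P)),
               reflected = as.vector(RF))
  })
  movie <- NULL
  if (render) {
    movie <- array(0, c(shape, n_frames))
    xs <- seq_len(shape[1]); ys <- seq_len(shape[2])
    for (k in seq_len(n_frames)) {
      fr <- truth[truth$frame == k, ]
      pl <- matrix(0, shape[1], shape[2])
      for (i in seq_len(nrow(fr)))
        pl <- pl + outer(exp(-(xs - fr$x_px[i])^2 / (2 * blob_sigma_px^2)),
                         exp(-(ys - fr$y_px[i])^2 / (2 * blob_sigma_px^2)))
      movie[, , k] <- if (dic) synth_dic(pl) else pl
    }
    attr(movie, "pitch_nm") <- rep(pitch_um * 1000, 2)
    attr(movie, "dt_s") <- dt_s
  }
  list(movie = movie, truth = truth,
       params = list(n = n, shape = shape, pitch_um = pitch_um, dt_s = dt_s,
                     n_frames = n_frames, speed_um_min = speed_um_min,
                     omega0_deg_min = omega0_deg_min, noise_deg = noise_deg,
                     blob_sigma_px = blob_sigma_px, seed = seed))
}
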