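#' Voxel-wise kinematics from five-frame displacement sets
#'
#' With `d_sf+`, `d_sf-`, `d_df+`, `d_df-` the four displacement fields of
#' a [five_frame_flowset()] (converted to micrometers), the symmetric
#' five-point stencils give, per voxel:
#'
#' * velocity `v = (8 (d_sf+ - d_sf-) - (d_df+ - d_df-)) / (12 dt)`
#' * acceleration `a = (d_sf+ + d_sf-) / dt^2`
#' * jerk `j = (d_df+ - 2 d_sf+ + 2 d_sf- - d_df-) / (2 dt^3)`
#'
#' All three are exact on cubic polynomial paths. The angular velocity is
#' the Frenet rotation rate of the motion direction,
#' `w = (v x a) / |v|^2`, and the Frenet triad is `T = v/|v|`,
#' `B = (v x a)/|v x a|`, `N = B x T`. Quantities depending on `|v|` or
#' `|v x a|` are masked (not NaN-filled) below numeric floors.
#'
#' Chirality signs: the world frame (x right, y down, z away from the
#' viewer) is right-handed, so `w . e > 0` means right-screw rotation about
#' the axis `e`, and in 2D a positive scalar angular velocity
#' `(v_x a_y - v_y a_x) / |v|^2` means clockwise rotation on screen.
#'
#' @name kinematics
NULL

flow_components <- function(f, nd) lapply(seq_len(nd), function(c2)
  array(f[slice.index(f, nd + 1) == c2], dim(f)[seq_len(nd)]))

cross_fields <- function(a, b) {
  list(a[[2]] * b[[3]] - a[[3]] * b[[2]],
       a[[3]] * b[[1]] - a[[1]] * b[[3]],
       a[[1]] * b[[2]] - a[[2]] * b[[1]])
}

#' Derive velocity, acceleration, jerk, angular velocity and Frenet triad
#'
#' @param flowset an `rtdic_flowset` (displacements in voxels).
#' @param dt frame interval in seconds.
#' @param pitch_um voxel pitch in micrometers (scalar or one per axis).
#'   Anisotropic pitch is honoured, but isotropic resampling beforehand is
#'   recommended.
#' @param tau_v motile-mask velocity floor in voxels/frame (default 0.2).
#' @param tau_i visible-mask intensity floor as a fraction of the center
#'   frame's maximum (default 0.1).
#' @return Object of class `rtdic_kin`: component lists `v`, `a`, `j`, `w`
#'   (micrometer/second units), `speed`, Frenet `T`, `N`, `B`, and logical
#'   masks `visible`, `motile`, `frenet_ok`.
#' @export
derive_kinematics <- function(flowset, dt, pitch_um = 1, tau_v = 0.2,
                              tau_i = 0.1) {
  stopifnot(inherits(flowset, "rtdic_flowset"), dt > 0)
  nd <- length(dim(flowset$center))
  pitch_um <- rep_len(pitch_um, nd)
  if (nd == 3 && max(pitch_um) / min(pitch_um) > 1.01)
    warning("anisotropic voxel pitch; consider resample_isotropic() first")
  to_um <- function(f) {
    cl <- flow_components(f, nd)
    Map(`*`, cl, as.list(pitch_um))
  }
  sfp <- to_um(flowset$sfp); sfm <- to_um(flowset$sfm)
  dfp <- to_um(flowset$dfp); dfm <- to_um(flowset$dfm)
  v <- Map(function(p1, m1, p2, m2) (8 * (p1 - m1) - (p2 - m2)) / (12 * dt),
           sfp, sfm, dfp, dfm)
  a <- Map(function(p1, m1) (p1 + m1) / dt^2, sfp, sfm)
  j <- Map(function(p2, p1, m1, m2) (p2 - 2 * p1 + 2 * m1 - m2) / (2 * dt^3),
           dfp, sfp, sfm, dfm)
  speed <- sqrt(Reduce(`+`, lapply(v, function(x) x^2)))
  if (nd == 3) {
    va <- cross_fields(v, a)
    va_n <- sqrt(Reduce(`+`, lapply(va, function(x) x^2)))
    spd2 <- pmax(speed^2, 1e-300)
    w <- lapply(va, function(x) x / spd2)
    Tf <- lapply(v, function(x) x / pmax(speed, 1e-300))
    Bf <- lapply(va, function(x) x / pmax(va_n, 1e-300))
    Nf <- cross_fields(Bf, Tf)
  } else {
    spd2 <- pmax(speed^2, 1e-300)
    w <- list(scalar = (v[[1]] * a[[2]] - v[[2]] * a[[1]]) / spd2)
    va_n <- abs(v[[1]] * a[[2]] - v[[2]] * a[[1]])
    Tf <- lapply(v, function(x) x / pmax(speed, 1e-300))
    Bf <- NULL
    Nf <- list(-Tf[[2]], Tf[[1]])
  }
  ctr <- flowset$center
  visible <- ctr >= tau_i * max(ctr)
  v_floor <- tau_v * min(pitch_um) / dt
  motile <- visible & (speed >= v_floor)
  frenet_ok <- motile & (va_n > 1e-12 * max(va_n, 1e-300))
  structure(list(v = v, a = a, j = j, w = w, speed = speed,
                 T = Tf, N = Nf, B = Bf,
                 visible = visible, motile = motile, frenet_ok = frenet_ok,
                 dt = dt, pitch_um = pitch_um, nd = nd,
                 intensity = ctr),
            class = "rtdic_kin")
}

#' @export
print.rtdic_kin <- function(x, ...) {
  cat(sprintf("rtdic kinematic field (%dD): %s voxels, %d visible, %d motile\n",
              x$nd, paste(dim(x$speed), collapse = " x "),
              sum(x$visible), sum(x$motile)))
  invisible(x)
}

project_onto <- function(comp_list, axis_list) {
  Reduce(`+`, Map(`*`, comp_list, axis_list))
}

#' Axial projections onto the local fiber direction
#'
#' Signed axial velocity `v . e` (positive = extension toward the tip,
#' negative = retraction) on visible-and-tractable voxels, and signed axial
#' angular velocity `w . e` (positive = right-screw about the base-to-tip
#' axis) on voxels that are additionally motile.
#'
#' @param kin an `rtdic_kin` (3D).
#' @param dirfield an `rtdic_dirfield` from [orient_to_tip()] (base-to-tip
#'   unit axes); its `valid` mask stands in for retrograde tractability.
#' @return List with arrays `axial_velocity` (um/s) and
#'   `axial_angular_velocity` (rad/s), `NA` outside their masks, and the
#'   masks themselves.
#' @export
local_axis_projection <- function(kin, dirfield) {
  stopifnot(kin$nd == 3)
  nd <- 3
  e <- flow_components(dirfield$e, nd)
  av <- project_onto(kin$v, e)
  aw <- project_onto(kin$w, e)
  m_v <- kin$visible & dirfield$valid
  m_w <- m_v & kin$motile
  av[!m_v] <- NA
  aw[!m_w] <- NA
  list(axial_velocity = av, axial_angular_velocity = aw,
       velocity_mask = m_v, angular_mask = m_w)
}

# Five-point stencil derivatives of a single tracked point path.
path_kinematics <- function(path, dt) {
  n <- nrow(path)
  idx <- 3:(n - 2)
  v <- (8 * (path[idx + 1, , drop = FALSE] - path[idx - 1, , drop = FALSE]) -
          (path[idx + 2, , drop = FALSE] - path[idx - 2, , drop = FALSE])) /
    (12 * dt)
  a <- (path[idx + 1, , drop = FALSE] + path[idx - 1, , drop = FALSE] -
          2 * path[idx, , drop = FALSE]) / dt^2
  w <- t(vapply(seq_along(idx), function(i) {
    vv <- v[i, ]; aa <- a[i, ]
    s2 <- sum(vv^2)
    if (s2 < 1e-300) return(rep(NA_real_, 3))
    cross3(vv, aa) / s2
  }, numeric(3)))
  list(frame = idx, v = v, a = a, w = w)
}

#' Chordal and orbital axial projections of a tracked point
#'
#' For a tracked point (e.g. a filopodium tip) with a tracked basal point:
#' the chordal axis is the chord from base to point; the orbital axis is
#' the fiber direction at the base. Velocity and angular velocity of the
#' point (five-point stencil along its path) are projected onto both axes.
#'
#' @param point_path n x 3 matrix of point positions (micrometers).
#' @param base_point length-3 base position, or an n x 3 matrix.
#' @param fiber_dir_at_base length-3 unit fiber direction at the base.
#' @param dt frame interval (seconds).
#' @return Data frame per interior frame: chordal/orbital axial velocity
#'   and angular velocity; rows where the point coincides with the base
#'   are `NA` (chordal axis undefined).
#' @export
chordal_orbital_axes <- function(point_path, base_point, fiber_dir_at_base,
                                 dt) {
  n <- nrow(point_path)
  if (n < 5) stop("need at least 5 tracked frames")
  if (is.null(dim(base_point)))
    base_point <- matrix(base_point, n, 3, byrow = TRUE)
  pk <- path_kinematics(point_path, dt)
  orb <- fiber_dir_at_base / vnorm(fiber_dir_at_base)
  out <- data.frame(frame = pk$frame, chordal_velocity = NA_real_,
                    chordal_angular_velocity = NA_real_,
                    orbital_velocity = NA_real_,
                    orbital_angular_velocity = NA_real_)
  for (i in seq_along(pk$frame)) {
    f <- pk$frame[i]
    chord <- point_path[f, ] - base_point[f, ]
    cn <- vnorm(chord)
    if (cn > 1e-9) {
      ch <- chord / cn
      out$chordal_velocity[i] <- sum(pk$v[i, ] * ch)
      out$chordal_angular_velocity[i] <- sum(pk$w[i, ] * ch)
    }
    out$orbital_velocity[i] <- sum(pk$v[i, ] * orb)
    out$orbital_angular_velocity[i] <- sum(pk$w[i, ] * orb)
  }
  out
}

#' Radial-axis projections about the intensity-weighted centroid
#'
#' The cell center is the intensity-weighted centroid of the volume; the
#' radial axis at each voxel is the outward unit vector from the centroid.
#' Projections are restricted to voxels whose tip certainty exceeds
#' `ct_threshold` (protrusion tips).
#'
#' @param kin an `rtdic_kin` (3D).
#' @param volume the intensity volume used for the centroid (defaults to
#'   the kinematic center frame).
#' @param ct tip-certainty array (from [certainties()]); `NULL` disables
#'   the tip restriction.
#' @param ct_threshold minimum tip certainty (default 0.2).
#' @return List with `radial_velocity`, `radial_angular_velocity`
#'   (masked arrays), the `centroid` (voxels), and the masks.
#' @export
radial_axis_projection <- function(kin, volume = NULL, ct = NULL,
                                   ct_threshold = 0.2) {
  stopifnot(kin$nd == 3)
  if (is.null(volume)) volume <- kin$intensity
  tot <- sum(volume)
  if (tot <= 0) stop("zero total intensity: centroid undefined")
  d <- dim(volume)
  coords <- as.matrix(expand.grid(lapply(d, seq_len)))
  centroid <- unname(colSums(coords * as.vector(volume)) / tot)
  r <- sweep(coords, 2, centroid, `-`)
  rn <- sqrt(rowSums(r^2))
  r <- r / pmax(rn, 1e-300)
  e <- lapply(1:3, function(c2) array(r[, c2], d))
  rv <- project_onto(kin$v, e)
  rw <- project_onto(kin$w, e)
  m <- kin$visible & array(rn > 0, d)
  if (!is.null(ct)) m <- m & (ct >= ct_threshold)
  m_w <- m & kin$motile
  rv[!m] <- NA
  rw[!m_w] <- NA
  list(radial_velocity = rv, radial_angular_velocity = rw,
       centroid = centroid, velocity_mask = m, angular_mask = m_w)
}

#' Pixel-wise 2D motility of a movie
#'
#' Runs the five-frame flow and kinematic stencils in 2D for every
#' interior frame of a movie. The scalar angular velocity
#' `(v_x a_y - v_y a_x)/|v|^2` is positive for clockwise rotation on
#' screen; the signed path curvature is `angular velocity / |v|`.
#'
#' @param movie 3D array `[x, y, t]` with at least 5 frames; attributes
#'   `pitch_nm` and `dt_s` are used unless overridden.
#' @param dt,pitch_um frame interval (s) and pixel pitch (um).
#' @param frames which center frames to analyze (defaults to all interior
#'   frames `3:(nt-2)`).
#' @param tau_v,tau_i mask floors as in [derive_kinematics()].
#' @param ... passed to [five_frame_flowset()].
#' @return List of per-frame results: each with `v` (um/s components),
#'   `speed`, `angular_velocity` (rad/s, clockwise positive),
#'   `curvature` (rad/um), and masks; plus a `summary` data.frame of
#'   per-frame masked means.
#' @export
pixelwise_2d_motility <- function(movie, dt = NULL, pitch_um = NULL,
                                  frames = NULL, tau_v = 0.2, tau_i = 0.1,
                                  ...) {
  d <- dim(movie)
  if (length(d) != 3) stop("movie must be [x, y, t]")
  nt <- d[3]
  if (nt < 5) stop("need at least 5 frames")
  if (is.null(dt)) dt <- attr(movie, "dt_s")
  if (is.null(pitch_um)) {
    p <- attr(movie, "pitch_nm")
    if (!is.null(p)) pitch_um <- p[1] / 1000
  }
  if (is.null(dt) || is.null(pitch_um))
    stop("dt and pitch_um must be supplied (or present as movie attributes)")
  if (is.null(frames)) frames <- 3:(nt - 2)
  res <- vector("list", length(frames))
  summ <- data.frame(frame = frames, mean_speed = NA_real_,
                     mean_angular_velocity = NA_real_,
                     mean_curvature = NA_real_)
  for (i in seq_along(frames)) {
    t0 <- frames[i]
    fs <- five_frame_flowset(movie[, , (t0 - 2):(t0 + 2)], ...)
    kin <- derive_kinematics(fs, dt, pitch_um, tau_v, tau_i)
    av <- kin$w$scalar
    curv <- av / pmax(kin$speed, 1e-300)
    m <- kin$motile
    av[!m] <- NA; curv[!m] <- NA
    res[[i]] <- list(frame = t0, v = kin$v, speed = kin$speed,
                     angular_velocity = av, curvature = curv,
                     visible = kin$visible, motile = m)
    summ$mean_speed[i] <- mean(kin$speed[m])
    summ$mean_angular_velocity[i] <- mean(av[m], na.rm = TRUE)
    summ$mean_curvature[i] <- mean(curv[m], na.rm = TRUE)
  }
  list(frames = res, summary = summ, dt = dt, pitch_um = pitch_um)
}
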