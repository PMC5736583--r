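#' Voxel-wise structure-tensor geometry
#'
#' The structure tensor `S = G_out * (grad I grad I^T)` — the outer-scale
#' smoothed second moment of the Gaussian-derivative gradient — encodes
#' local shape at each voxel. Its sorted eigen system
#' (`lambda1 >= lambda2 >= lambda3`, eigenvectors `e1..e3`) distinguishes
#' spheres (all eigenvalues equal), fibers (`lambda3` small, `e3` = fiber
#' axis) and planes. The polarity vector `P = G_out * grad I` (magnitude
#' `lambda_p`, direction `e_p`) marks fiber end-points: at a tip the local
#' gradients do not cancel, so `lambda_p` is large and `e_p` aligns with
#' the fiber axis.
#'
#' Certainty indices (computed by [certainties()]):
#' * fiber certainty `Ca = (lambda2 - lambda3) / (lambda1 + eps)`, high on
#'   fiber trunks, zero on background and blobs;
#' * tip certainty `Ct = |e_p . e3| * min(lambda_p / mean(lambda_p), 1) * Ca`,
#'   peaking at fiber end-caps.
#'
#' Both are clipped to `[0, 1]`; voxels whose tensor trace falls below a
#' relative floor are zeroed. The regularizer `eps` is `1e-3 * max(lambda1)`.
#'
#' @name structure_tensor
NULL

#' Compute the structure tensor field of a volume or plane
#'
#' @param volume 2D matrix or 3D array of intensities.
#' @param sigma_in inner (derivative) scale in voxels.
#' @param sigma_out outer (integration) scale in voxels; the "diameter of
#'   interest" — about 0.6 um for filopodium-scale protrusions.
#' @param floor_frac relative tensor-trace floor below which eigen analysis
#'   is skipped and certainties are zero (default `1e-4`).
#' @return An object of class `rtdic_tensor`: list with eigenvalue arrays
#'   `lam1..lamD`, eigenvector arrays `e1..eD` (each `[dims, D]`), polarity
#'   magnitude `lamp` and direction `ep`, the tensor components `S`, the
#'   valid-voxel mask, and the scales.
#' @export
compute_tensor <- function(volume, sigma_in = 1, sigma_out = 3,
                           floor_frac = 1e-4) {
  if (!(sigma_out >= sigma_in && sigma_in > 0))
    stop("need sigma_out >= sigma_in > 0")
  d <- dim(volume)
  nd <- length(d)
  if (!nd %in% 2:3) stop("volume must be 2D or 3D")
  if (any(d < 6 * sigma_out))
    stop("volume smaller than 6 * sigma_out along some axis")
  dk <- gaussian_deriv_kernel(sigma_in)
  sk <- gaussian_kernel(sigma_in)
  grad <- vector("list", nd)
  for (ax in seq_len(nd)) {
    g <- convolve_dim(volume, dk$k, dk$o, ax)
    for (other in setdiff(seq_len(nd), ax))
      g <- convolve_dim(g, sk$k, sk$o, other)
    grad[[ax]] <- g
  }
  ok <- gaussian_kernel(sigma_out)
  smooth_out <- function(a) {
    for (ax in seq_len(nd)) a <- convolve_dim(a, ok$k, ok$o, ax)
    a
  }
  S <- list()
  for (i in seq_len(nd)) for (j in i:nd)
    S[[paste0("s", i, j)]] <- smooth_out(grad[[i]] * grad[[j]])
  P <- lapply(grad, smooth_out)
  Pmat <- do.call(cbind, lapply(P, as.vector))
  lamp <- sqrt(rowSums(Pmat^2))
  ep <- Pmat / pmax(lamp, 1e-300)
  tr <- Reduce(`+`, S[paste0("s", seq_len(nd), seq_len(nd))])
  valid <- as.vector(tr) > floor_frac * max(tr)
  n <- prod(d)
  lam <- matrix(0, n, nd)
  evec <- lapply(seq_len(nd), function(i) matrix(0, n, nd))
  if (nd == 2) {
    a <- as.vector(S$s11); b <- as.vector(S$s12); c2 <- as.vector(S$s22)
    half_tr <- (a + c2) / 2
    disc <- sqrt(pmax(((a - c2) / 2)^2 + b^2, 0))
    lam[, 1] <- half_tr + disc
    lam[, 2] <- pmax(half_tr - disc, 0)
    # eigenvector of the larger eigenvalue; pick the numerically stable form
    vx <- ifelse(abs(b) > 1e-300, b, lam[, 1] - c2)
    vy <- ifelse(abs(b) > 1e-300, lam[, 1] - a, b)
    deg <- abs(vx) + abs(vy) < 1e-300
    vx[deg] <- 1; vy[deg] <- 0
    nn <- sqrt(vx^2 + vy^2)
    evec[[1]] <- cbind(vx / nn, vy / nn)
    evec[[2]] <- cbind(-evec[[1]][, 2], evec[[1]][, 1])
  } else {
    idx <- which(valid)
    s11 <- as.vector(S$s11); s12 <- as.vector(S$s12); s13 <- as.vector(S$s13)
    s22 <- as.vector(S$s22); s23 <- as.vector(S$s23); s33 <- as.vector(S$s33)
    for (v in idx) {
      M <- matrix(c(s11[v], s12[v], s13[v],
                    s12[v], s22[v], s23[v],
                    s13[v], s23[v], s33[v]), 3, 3)
      es <- eigen(M, symmetric = TRUE)
      lam[v, ] <- pmax(es$values, 0)
      for (k in 1:3) evec[[k]][v, ] <- es$vectors[, k]
    }
  }
  lam[!valid, ] <- 0
  structure(list(
    dim = d,
    lam = lapply(seq_len(nd), function(k) array(lam[, k], d)),
    evec = lapply(seq_len(nd), function(k) array(evec[[k]], c(d, nd))),
    lamp = array(lamp, d),
    ep = array(ep, c(d, nd)),
    S = S,
    valid = array(valid, d),
    sigma_in = sigma_in, sigma_out = sigma_out,
    eps = 1e-3 * max(lam[, 1])
  ), class = "rtdic_tensor")
}

#' @export
print.rtdic_tensor <- function(x, ...) {
  cat("rtdic structure tensor field:", paste(x$dim, collapse = " x "),
      sprintf("(sigma_in %.2f, sigma_out %.2f vox; %d valid voxels)\n",
              x$sigma_in, x$sigma_out, sum(x$valid)))
  invisible(x)
}

#' Fiber and tip certainty indices
#'
#' See [structure_tensor] for the definitions. `mean(lambda_p)` is taken
#' over valid voxels.
#'
#' @param tf an `rtdic_tensor` from [compute_tensor()].
#' @return `tf` with arrays `Ca` and `Ct` added.
#' @export
certainties <- function(tf) {
  nd <- length(tf$dim)
  lam1 <- tf$lam[[1]]
  lamlo <- tf$lam[[nd]]
  lam2 <- tf$lam[[nd - 1]]
  Ca <- (lam2 - lamlo) / (lam1 + tf$eps)
  Ca[!tf$valid] <- 0
  Ca <- pmin(pmax(Ca, 0), 1)
  lamp_bar <- mean(tf$lamp[tf$valid])
  if (!is.finite(lamp_bar)) lamp_bar <- 0
  e_fiber <- tf$evec[[nd]]
  align <- array(0, tf$dim)
  flat_e <- matrix(e_fiber, ncol = nd)
  flat_p <- matrix(tf$ep, ncol = nd)
  align[] <- abs(rowSums(flat_e * flat_p))
  if (lamp_bar > 0) {
    Ct <- align * pmin(tf$lamp / lamp_bar, 1) * Ca
  } else {
    Ct <- array(0, tf$dim)
  }
  Ct[!tf$valid] <- 0
  tf$Ca <- Ca
  tf$Ct <- pmin(pmax(Ct, 0), 1)
  tf
}

#' Orient fiber axes away from a base region
#'
#' The fiber eigenvector is defined only up to sign; this resolves the
#' `+/-e3` (or `+/-e2` in 2D) ambiguity so the axis points from the base
#' (cell body / re-aggregate centroid) toward the distal tip, by aligning
#' each axis with the outward radial direction from the base point. Voxels
#' whose fiber axis is nearly perpendicular to the outward direction (no
#' reliable sign) or that are invalid are masked.
#'
#' @param tf an `rtdic_tensor`.
#' @param base numeric base point in voxel coordinates (length 2 or 3).
#' @param min_dot minimum `|axis . radial|` for a defined orientation
#'   (default 0.05).
#' @return List of class `rtdic_dirfield`: `e` (`[dims, D]` oriented unit
#'   axes) and `valid` mask.
#' @export
orient_to_tip <- function(tf, base, min_dot = 0.05) {
  nd <- length(tf$dim)
  stopifnot(length(base) == nd)
  e <- matrix(tf$evec[[nd]], ncol = nd)
  coords <- as.matrix(expand.grid(lapply(tf$dim, seq_len)))
  r <- sweep(coords, 2, base, `-`)
  rn <- sqrt(rowSums(r^2))
  r <- r / pmax(rn, 1e-300)
  dt <- rowSums(e * r)
  sgn <- sign(dt)
  e <- e * ifelse(sgn == 0, 1, sgn)
  valid <- as.vector(tf$valid) & abs(dt) >= min_dot & rn > 0
  structure(list(e = array(e, c(tf$dim, nd)),
                 valid = array(valid, tf$dim), base = base),
            class = "rtdic_dirfield")
}

#' Trace a voxel backward along the fiber direction
#'
#' Integrates the negated tip-oriented fiber axis from a start voxel with
#' sub-voxel steps (linear interpolation of the direction field). The voxel
#' is "tractable" — i.e. belongs to a genuine protrusion — if the path
#' reaches the base region within `max_steps` while fiber certainty stays
#' above `ca_threshold`.
#'
#' @param start numeric start voxel (length D).
#' @param tf an `rtdic_tensor` with certainties ([certainties()]).
#' @param dirfield an `rtdic_dirfield` from [orient_to_tip()].
#' @param base_radius radius (voxels) around the dirfield base that counts
#'   as arrival.
#' @param step step length in voxels (max 0.5).
#' @param max_steps maximum number of steps.
#' @param ca_threshold minimum fiber certainty along the path.
#' @return List with `path` (matrix of visited positions), `tractable`
#'   flag, and `arc_length`.
#' @export
retrograde_trace <- function(start, tf, dirfield, base_radius = 3,
                             step = 0.5, max_steps = 400,
                             ca_threshold = 0.05) {
  step <- min(step, 0.5)
  nd <- length(tf$dim)
  e_flat <- matrix(dirfield$e, ncol = nd)
  pos <- as.numeric(start)
  path <- matrix(pos, 1, nd)
  base <- dirfield$base
  tract <- FALSE
  for (k in seq_len(max_steps)) {
    if (any(pos < 1) || any(pos > tf$dim)) break
    ca <- interp_linear(tf$Ca, matrix(pos, 1))
    if (ca < ca_threshold) break
    dir <- vapply(seq_len(nd), function(c2)
      interp_linear(array(e_flat[, c2], tf$dim), matrix(pos, 1)), numeric(1))
    nn <- vnorm(dir)
    if (nn < 1e-6) break
    pos <- pos - step * dir / nn
    path <- rbind(path, pos)
    if (vnorm(pos - base) <= base_radius) { tract <- TRUE; break }
  }
  list(path = path, tractable = tract,
       arc_length = step * (nrow(path) - 1))
}

#' Signed fiber curvature of a 2D image
#'
#' The in-plane fiber tangent (structure-tensor eigenvector of the smaller
#' eigenvalue) is oriented outward from a center point; the curvature is
#' the directional derivative of the tangent angle along the tangent
#' itself. Sign convention (display coordinates, y down): positive =
#' the fiber turns clockwise on screen while moving outward, negative =
#' counterclockwise. This is the package-wide chirality convention.
#'
#' @param plane 2D intensity image (e.g. an RT-DIC converted neurite
#'   field).
#' @param center `c(x, y)` center (pixels) from which "outward" is
#'   defined, e.g. the re-aggregate centroid.
#' @param sigma_in,sigma_out tensor scales (pixels).
#' @param ca_threshold fiber-certainty mask threshold (default 0.2).
#' @param pitch_nm pixel pitch; when supplied, curvature is returned in
#'   rad/mm, otherwise rad/pixel.
#' @return List with `kappa` (signed curvature, masked voxels `NA`),
#'   `mask` (fiber voxels), `Ca`, and the tangent field `t`.
#' @export
signed_curvature_2d <- function(plane, center, sigma_in = 1.5,
                                sigma_out = 4, ca_threshold = 0.2,
                                pitch_nm = NULL) {
  tf <- certainties(compute_tensor(plane, sigma_in, sigma_out))
  d <- dim(plane)
  e2 <- matrix(tf$evec[[2]], ncol = 2)
  coords <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2])))
  r <- sweep(coords, 2, center, `-`)
  rn <- sqrt(rowSums(r^2))
  r <- r / pmax(rn, 1e-300)
  dt <- rowSums(e2 * r)
  e2 <- e2 * ifelse(sign(dt) == 0, 1, sign(dt))
  txf <- array(e2[, 1], d); tyf <- array(e2[, 2], d)
  # kappa = t . grad(psi) with grad(psi) = t_x grad(t_y) - t_y grad(t_x)
  dtx_x <- central_diff(txf, 1); dtx_y <- central_diff(txf, 2)
  dty_x <- central_diff(tyf, 1); dty_y <- central_diff(tyf, 2)
  dpsi_x <- txf * dty_x - tyf * dtx_x
  dpsi_y <- txf * dty_y - tyf * dtx_y
  kappa <- txf * dpsi_x + tyf * dpsi_y
  mask <- tf$Ca >= ca_threshold & abs(array(dt, d)) >= 0.05
  kappa[!mask] <- NA
  unit <- "rad/px"
  if (!is.null(pitch_nm)) {
    kappa <- kappa / (pitch_nm[1] * 1e-6)  # rad/px -> rad/mm
    unit <- "rad/mm"
  }
  list(kappa = kappa, mask = mask, Ca = tf$Ca,
       t = array(e2, c(d, 2)), unit = unit)
}
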