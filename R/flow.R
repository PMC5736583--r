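#' Dense Horn-Schunck optical flow (2D and 3D)
#'
#' Horn-Schunck flow minimizes brightness-constancy violation plus a
#' smoothness penalty `alpha^2 |grad u|^2`. The Jacobi iteration is
#'
#' `u <- ubar - grad(I) * (grad(I) . ubar + I_t) / (alpha^2 + |grad I|^2)`
#'
#' where `ubar` is the neighbour mean of the current flow (6-neighbour in
#' 3D, 4-neighbour in 2D; Neumann boundaries). Spatial derivatives are
#' central differences averaged over the two frames; `I_t = I1 - I0`.
#' Large displacements are handled by coarse-to-fine estimation over
#' Gaussian pyramids ([pyramid_flow()]), warping the second frame back by
#' the upsampled flow at each level.
#'
#' @name optical_flow
NULL

neighbour_mean <- function(a) {
  nd <- length(dim(a))
  s <- array(0, dim(a))
  for (ax in seq_len(nd))
    s <- s + take_shifted(a, 1L, ax) + take_shifted(a, -1L, ax)
  s / (2 * nd)
}

#' @rdname optical_flow
#' @param frame0,frame1 numeric arrays of identical shape (2D or 3D).
#' @param alpha regularization weight (default 0.2; intensities are assumed
#'   pre-normalized to about `[0, 1]`).
#' @param n_iter maximum Jacobi iterations per call (default 300).
#' @param tol stop when the RMS flow update falls below `tol`
#'   (default 1e-5 voxels).
#' @param init optional initial flow array `[dims, D]`.
#' @return Flow array `[dims, D]` (displacement in voxels, frame0 to
#'   frame1), with attribute `residuals` (per-iteration RMS updates).
#' @export
horn_schunck <- function(frame0, frame1, alpha = 0.2, n_iter = 300,
                         tol = 1e-5, init = NULL) {
  if (!all(is.finite(frame0)) || !all(is.finite(frame1)))
    stop("frames must be finite")
  d <- dim(frame0)
  if (!all(d == dim(frame1))) stop("frames must share a shape")
  nd <- length(d)
  stopifnot(alpha > 0)
  g <- lapply(seq_len(nd), function(ax)
    (central_diff(frame0, ax) + central_diff(frame1, ax)) / 2)
  It <- frame1 - frame0
  denom <- alpha^2 + Reduce(`+`, lapply(g, function(x) x^2))
  u <- vector("list", nd)
  for (c2 in seq_len(nd))
    u[[c2]] <- if (is.null(init)) array(0, d) else
      array(init[slice.index(init, nd + 1) == c2], d)
  residuals <- numeric(0)
  for (it in seq_len(n_iter)) {
    ub <- lapply(u, neighbour_mean)
    proj <- Reduce(`+`, Map(`*`, g, ub)) + It
    upd <- proj / denom
    delta2 <- 0
    for (c2 in seq_len(nd)) {
      newu <- ub[[c2]] - g[[c2]] * upd
      delta2 <- delta2 + mean((newu - u[[c2]])^2)
      u[[c2]] <- newu
    }
    residuals <- c(residuals, sqrt(delta2))
    if (residuals[it] < tol) break
  }
  flow <- array(unlist(u), c(d, nd))
  attr(flow, "residuals") <- residuals
  flow
}

# Blur with sigma = 1 voxel and take every second sample along each axis.
pyr_down <- function(a) {
  a <- gaussian_blur(a, 1, boundary = "replicate")
  d <- dim(a)
  for (ax in seq_along(d)) a <- index_dim(a, seq(1, d[ax], by = 2), ax)
  a
}

# Resample a flow field to a finer grid, scaling displacement values by
# the size ratio per axis.
upsample_flow <- function(flow, new_dim) {
  d <- dim(flow)
  nd <- length(d) - 1
  old_dim <- d[seq_len(nd)]
  coords <- as.matrix(expand.grid(lapply(new_dim, seq_len)))
  src <- coords
  for (ax in seq_len(nd))
    src[, ax] <- (coords[, ax] - 1) * (old_dim[ax] - 1) /
      max(new_dim[ax] - 1, 1) + 1
  out <- array(0, c(new_dim, nd))
  flat <- matrix(flow, ncol = nd)
  scale <- (new_dim - 1) / pmax(old_dim - 1, 1)
  for (c2 in seq_len(nd)) {
    comp <- array(flat[, c2], old_dim)
    out[slice.index(out, nd + 1) == c2] <-
      interp_linear(comp, src) * scale[c2]
  }
  out
}

# Sample `a` at positions x + flow(x) (clamped).
warp_by_flow <- function(a, flow) {
  d <- dim(a)
  nd <- length(d)
  coords <- as.matrix(expand.grid(lapply(d, seq_len)))
  flat <- matrix(flow, ncol = nd)
  out <- interp_linear(a, coords + flat)
  array(out, d)
}

#' @rdname optical_flow
#' @param levels number of pyramid levels; `NULL` (default) uses
#'   `max(1, floor(log2(min(dim) / 16)) + 1)`.
#' @param n_warp warping refinements per level (default 3): the second
#'   frame is re-warped by the current flow and an increment is estimated,
#'   which removes the one-sided linearization bias of a single
#'   Horn-Schunck solve.
#' @export
pyramid_flow <- function(frame0, frame1, levels = NULL, alpha = 0.2,
                         n_iter = 300, tol = 1e-5, n_warp = 3) {
  d <- dim(frame0)
  nd <- length(d)
  if (is.null(levels)) levels <- max(1L, floor(log2(min(d) / 16)) + 1L)
  p0 <- list(frame0); p1 <- list(frame1)
  lv <- 1
  while (lv < levels && min(dim(p0[[lv]])) >= 16) {
    p0[[lv + 1]] <- pyr_down(p0[[lv]])
    p1[[lv + 1]] <- pyr_down(p1[[lv]])
    lv <- lv + 1
  }
  flow <- NULL
  for (l in rev(seq_len(lv))) {
    f0 <- p0[[l]]; f1 <- p1[[l]]
    if (!is.null(flow)) flow <- upsample_flow(flow, dim(f0))
    for (w in seq_len(n_warp)) {
      if (is.null(flow)) {
        flow <- horn_schunck(f0, f1, alpha, n_iter, tol)
      } else {
        f1w <- warp_by_flow(f1, flow)
        inc <- horn_schunck(f0, f1w, alpha, n_iter, tol)
        flow <- flow + inc
        if (sqrt(mean(inc^2)) < tol) break
      }
    }
  }
  flow
}

#' Four displacement fields from five sequential frames
#'
#' From frames `t-2 .. t+2`, estimates the four displacement sets on the
#' grid of the center frame: single-frame forward (`sfp`, t to t+1),
#' single-frame backward (`sfm`, t to t-1), double-frame forward (`dfp`, t
#' to t+2) and double-frame backward (`dfm`, t to t-2). These are the
#' inputs to the five-point kinematic stencils in [derive_kinematics()].
#'
#' @param frames list of exactly five arrays, or an array whose last
#'   dimension has length 5.
#' @param levels,alpha,n_iter,tol passed to [pyramid_flow()].
#' @return Object of class `rtdic_flowset`: list with `sfp`, `sfm`, `dfp`,
#'   `dfm` (each `[dims, D]`) and the center frame.
#' @export
five_frame_flowset <- function(frames, levels = NULL, alpha = 0.2,
                               n_iter = 300, tol = 1e-5) {
  if (is.array(frames) && !is.list(frames)) {
    nd <- length(dim(frames))
    if (dim(frames)[nd] != 5)
      stop("need exactly 5 frames; the first/last two time points of a movie yield no kinematics")
    frames <- lapply(1:5, function(k) {
      a <- index_dim(frames, k, nd)
      array(a, dim(frames)[-nd])
    })
  }
  if (length(frames) != 5)
    stop("need exactly 5 frames; the first/last two time points of a movie yield no kinematics")
  ctr <- frames[[3]]
  fl <- function(target) pyramid_flow(ctr, target, levels, alpha, n_iter, tol)
  structure(list(sfp = fl(frames[[4]]), sfm = fl(frames[[2]]),
                 dfp = fl(frames[[5]]), dfm = fl(frames[[1]]),
                 center = ctr),
            class = "rtdic_flowset")
}
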