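# Shared fixtures and independent oracles, all generated in code.

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Isotropic Gaussian blob sampled at voxel centers.
blob3d <- function(center, shape = c(24, 24, 24), sigma = 2.5) {
  outer(outer(exp(-(seq_len(shape[1]) - center[1])^2 / (2 * sigma^2)),
              exp(-(seq_len(shape[2]) - center[2])^2 / (2 * sigma^2))),
        exp(-(seq_len(shape[3]) - center[3])^2 / (2 * sigma^2)))
}

# Smooth random texture covering the volume (for translation-recovery
# tests where every voxel carries signal).
texture3d <- function(shape, sigma = 1.5, seed = 42) {
  set.seed(seed)
  a <- array(rnorm(prod(shape)), shape)
  k <- exp(-(-6:6)^2 / (2 * sigma^2)); k <- k / sum(k)
  for (ax in seq_along(shape)) {
    idx <- function(i, n) ((i - 1) %% n) + 1
    out <- array(0, dim(a))
    n <- dim(a)[ax]
    for (j in seq_along(k)) {
      sel <- idx(seq_len(n) + (j - 7), n)
      args <- rep(list(quote(expr = )), length(shape))
      args[[ax]] <- sel
      out <- out + k[j] * do.call(`[`, c(list(a), args, list(drop = FALSE)))
    }
    a <- out
  }
  (a - min(a)) / (max(a) - min(a))
}

circshift3 <- function(a, k, ax) {
  n <- dim(a)[ax]
  idx <- ((seq_len(n) - 1 - k) %% n) + 1
  args <- rep(list(quote(expr = )), length(dim(a)))
  args[[ax]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# Independent brute-force implementation of one 3D Horn-Schunck Jacobi
# iteration (plain voxel loops; Neumann boundaries), used as the oracle
# for the vectorized solver.
hs_one_iter_bruteforce <- function(f0, f1, alpha, u) {
  d <- dim(f0)
  cl <- function(i, n) min(max(i, 1L), n)
  g <- array(0, c(d, 3)); It <- f1 - f0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g[x, y, z, 1] <- ((f0[cl(x + 1, d[1]), y, z] - f0[cl(x - 1, d[1]), y, z]) +
                        (f1[cl(x + 1, d[1]), y, z] - f1[cl(x - 1, d[1]), y, z])) / 4
    g[x, y, z, 2] <- ((f0[x, cl(y + 1, d[2]), z] - f0[x, cl(y - 1, d[2]), z]) +
                        (f1[x, cl(y + 1, d[2]), z] - f1[x, cl(y - 1, d[2]), z])) / 4
    g[x, y, z, 3] <- ((f0[x, y, cl(z + 1, d[3])] - f0[x, y, cl(z - 1, d[3])]) +
                        (f1[x, y, cl(z + 1, d[3])] - f1[x, y, cl(z - 1, d[3])]) ) / 4
  }
  un <- u
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    ub <- numeric(3)
    for (c2 in 1:3) {
      ub[c2] <- (u[cl(x + 1, d[1]), y, z, c2] + u[cl(x - 1, d[1]), y, z, c2] +
                   u[x, cl(y + 1, d[2]), z, c2] + u[x, cl(y - 1, d[2]), z, c2] +
                   u[x, y, cl(z + 1, d[3]), c2] + u[x, y, cl(z - 1, d[3]), c2]) / 6
    }
    gg <- g[x, y, z, ]
    upd <- (sum(gg * ub) + It[x, y, z]) / (alpha^2 + sum(gg^2))
    un[x, y, z, ] <- ub - gg * upd
  }
  un
}

# Synthetic flowset with spatially uniform displacements taken from an
# analytic path p(t) (micrometer units assumed handled by caller).
flowset_from_path <- function(p_fun, t0, dt, shape = c(6, 6, 6),
                              center_frame = NULL) {
  mk <- function(k) {
    arr <- array(0, c(shape, 3))
    d <- p_fun(t0 + k * dt) - p_fun(t0)
    for (c2 in 1:3) arr[, , , c2] <- d[c2]
    arr
  }
  ctr <- if (is.null(center_frame)) array(1, shape) else center_frame
  structure(list(sfp = mk(1), sfm = mk(-1), dfp = mk(2), dfm = mk(-2),
                 center = ctr), class = "rtdic_flowset")
}

flowset_from_path_2d <- function(p_fun, t0, dt, shape = c(6, 6)) {
  mk <- function(k) {
    arr <- array(0, c(shape, 2))
    d <- p_fun(t0 + k * dt) - p_fun(t0)
    for (c2 in 1:2) arr[, , c2] <- d[c2]
    arr
  }
  structure(list(sfp = mk(1), sfm = mk(-1), dfp = mk(2), dfm = mk(-2),
                 center = array(1, shape)), class = "rtdic_flowset")
}

# Soft cylinder along unit axis u through point p0.
cylinder3d <- function(shape, p0, u, radius, half_len) {
  u <- u / sqrt(sum(u^2))
  co <- as.matrix(expand.grid(seq_len(shape[1]), seq_len(shape[2]),
                              seq_len(shape[3])))
  rel <- sweep(co, 2, p0, `-`)
  s <- rel %*% u
  perp2 <- rowSums(rel^2) - s^2
  v <- exp(-perp2 / (2 * radius^2)) / (1 + exp(4 * (abs(s) - half_len)))
  array(v, shape)
}
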