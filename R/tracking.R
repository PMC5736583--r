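#' Cell segmentation and tracking in 2D RT-DIC movies
#'
#' Converted (self-luminous) movies are segmented frame-by-frame with a
#' marker-based watershed on the smoothed intensity ([segment_cells()]),
#' centroids are linked across frames with optical-flow-assisted greedy
#' nearest-neighbour assignment ([link_tracks()]), and per-cell chirality
#' is quantified from angular displacements of the heading
#' ([chirality_stats()]). Heading convention: display coordinates (y
#' down); a positive angular displacement is clockwise on screen.
#'
#' @name tracking2d
NULL

#' Segment cells in one RT-DIC intensity plane
#'
#' Watershed transform of the Gaussian-smoothed intensity, restricted to
#' the foreground above the Otsu threshold; the watershed tolerance acts
#' as an h-maxima marker depth, merging peaks shallower than
#' `h_frac * dynamic range`.
#'
#' @param plane 2D intensity image (self-luminous, bright cells).
#' @param smooth_sigma Gaussian smoothing s.d. in pixels (default 2).
#' @param h_frac marker depth as a fraction of the dynamic range
#'   (default 0.1).
#' @return List with `labels` (integer label matrix, 0 = background) and
#'   `centroids` (data.frame: label, x, y intensity-weighted centroid in
#'   pixels, area in pixels).
#' @export
segment_cells <- function(plane, smooth_sigma = 2, h_frac = 0.1) {
  sm <- gaussian_blur(plane, smooth_sigma, dims = 1:2)
  rng <- range(sm)
  if (rng[2] <= rng[1]) {
    return(list(labels = matrix(0L, nrow(plane), ncol(plane)),
                centroids = data.frame(label = integer(), x = numeric(),
                                       y = numeric(), area = numeric())))
  }
  smn <- (sm - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(smn))
  mask <- smn > thr
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(plane), ncol(plane)),
                centroids = data.frame(label = integer(), x = numeric(),
                                       y = numeric(), area = numeric())))
  }
  labels <- EBImage::watershed(EBImage::Image(smn * mask),
                               tolerance = h_frac, ext = 1)
  labels <- EBImage::imageData(labels)
  storage.mode(labels) <- "integer"
  n <- max(labels)
  cents <- data.frame(label = integer(), x = numeric(), y = numeric(),
                      area = numeric())
  if (n > 0) {
    w <- as.vector(plane - min(plane)) + 1e-12
    lab_v <- as.vector(labels)
    xx <- as.vector(row(plane)); yy <- as.vector(col(plane))
    keep <- lab_v > 0
    sw <- tapply(w[keep], lab_v[keep], sum)
    sx <- tapply((w * xx)[keep], lab_v[keep], sum)
    sy <- tapply((w * yy)[keep], lab_v[keep], sum)
    ar <- tabulate(lab_v[keep], n)
    cents <- data.frame(label = as.integer(names(sw)),
                        x = as.numeric(sx / sw), y = as.numeric(sy / sw),
                        area = ar[as.integer(names(sw))])
  }
  list(labels = labels, centroids = cents)
}

#' Link per-frame particles into cell tracks
#'
#' Each particle's centroid is advanced by the mean optical-flow
#' displacement within its mask (when flow is supplied) to predict its
#' next-frame position; predictions and detections are matched greedily in
#' order of increasing distance under a gate. Unmatched detections start
#' new tracks; unmatched predictions terminate theirs (a particle
#' re-appearing later starts a fresh track).
#'
#' @param segmented list of per-frame [segment_cells()] results.
#' @param flows optional list of flow fields (`[x, y, 2]`, frame `t` to
#'   `t+1`, length `nframes - 1`) from [pyramid_flow()].
#' @param gate_px assignment gate in pixels; `NULL` (default) uses twice
#'   the median matched step once available, starting from `gate_init`.
#' @param gate_init initial gate in pixels (default 10).
#' @return Data frame with one row per particle per frame: `track`,
#'   `frame`, `label`, `x`, `y` (pixels), `area`; attribute `events`
#'   counts starts/terminations/ambiguous assignments per frame.
#' @export
link_tracks <- function(segmented, flows = NULL, gate_px = NULL,
                        gate_init = 10) {
  nt <- length(segmented)
  out <- list()
  events <- data.frame(frame = seq_len(nt), started = 0L, matched = 0L,
                       terminated = 0L)
  cents <- segmented[[1]]$centroids
  track_ids <- seq_len(nrow(cents))
  next_id <- nrow(cents) + 1L
  steps <- numeric(0)
  out[[1]] <- cbind(data.frame(track = track_ids,
                               frame = rep(1L, nrow(cents))), cents)
  events$started[1] <- nrow(cents)
  for (t in seq_len(nt - 1)) {
    prev <- segmented[[t]]$centroids
    cur <- segmented[[t + 1]]$centroids
    pred <- prev
    if (!is.null(flows) && nrow(prev) > 0) {
      fl <- flows[[t]]
      lab <- segmented[[t]]$labels
      for (i in seq_len(nrow(prev))) {
        m <- lab == prev$label[i]
        if (any(m)) {
          pred$x[i] <- prev$x[i] + mean(fl[, , 1][m])
          pred$y[i] <- prev$y[i] + mean(fl[, , 2][m])
        }
      }
    }
    gate <- if (!is.null(gate_px)) gate_px else
      if (length(steps) >= 5) 2 * stats::median(steps) else gate_init
    assign_cur <- rep(NA_integer_, nrow(cur))
    if (nrow(prev) > 0 && nrow(cur) > 0) {
      dmat <- outer(pred$x, cur$x, `-`)^2 + outer(pred$y, cur$y, `-`)^2
      dmat <- sqrt(dmat)
      ord <- order(dmat)
      used_p <- logical(nrow(prev)); used_c <- logical(nrow(cur))
      for (o in ord) {
        if (dmat[o] > gate) break
        i <- (o - 1) %% nrow(prev) + 1
        k <- (o - 1) %/% nrow(prev) + 1
        if (used_p[i] || used_c[k]) next
        used_p[i] <- TRUE; used_c[k] <- TRUE
        assign_cur[k] <- i
        steps <- c(steps, sqrt((prev$x[i] - cur$x[k])^2 +
                                 (prev$y[i] - cur$y[k])^2))
      }
    }
    new_ids <- integer(nrow(cur))
    for (k in seq_len(nrow(cur))) {
      if (!is.na(assign_cur[k])) {
        new_ids[k] <- track_ids[assign_cur[k]]
      } else {
        new_ids[k] <- next_id
        next_id <- next_id + 1L
      }
    }
    events$matched[t + 1] <- sum(!is.na(assign_cur))
    events$started[t + 1] <- sum(is.na(assign_cur))
    events$terminated[t + 1] <- nrow(prev) - sum(!is.na(assign_cur))
    out[[t + 1]] <- cbind(data.frame(track = new_ids,
                                     frame = rep(t + 1L, nrow(cur))), cur)
    track_ids <- new_ids
  }
  res <- do.call(rbind, out)
  attr(res, "events") <- events
  res
}

#' Per-track and per-culture chirality statistics
#'
#' Per step (above a minimum-displacement gate): heading
#' `phi = atan2(dy, dx)` in display coordinates and angular displacement
#' `dphi` wrapped to (-180, 180], clockwise positive. Per track: mean
#' angular velocity (deg/min), signed trajectory curvature (rad/mm, mean
#' of `dphi` in radians over step length), speed, and the cumulative
#' angular displacement curve. Per culture: mean, s.d., and s.e.m. of the
#' track means with the two-tier tests of [trial_summary()] /
#' [across_trial_test()] left to the caller.
#'
#' @param tracks data frame from [link_tracks()] (or ground-truth tracks
#'   with columns `track`/`id`, `frame`, `x`, `y`).
#' @param dt_s frame interval (seconds).
#' @param pitch_um pixel pitch (micrometers); if tracks are already in
#'   micrometers use `pitch_um = 1` and micrometer columns.
#' @param min_step_px minimum displacement (pixels) for a step to
#'   contribute a heading (default 0.5).
#' @param min_steps tracks with fewer valid steps are dropped (default 3).
#' @return List with `per_track` (data.frame: track, n_steps,
#'   mean_angular_velocity_deg_min, curvature_rad_mm, speed_um_min),
#'   `steps` (per-step table with `dphi_deg` and cumulative angle), and
#'   `summary` (mean/sd/sem over tracks).
#' @export
chirality_stats <- function(tracks, dt_s, pitch_um, min_step_px = 0.5,
                            min_steps = 3) {
  id_col <- if ("track" %in% names(tracks)) "track" else "id"
  x_col <- if ("x" %in% names(tracks)) "x" else "x_px"
  y_col <- if ("y" %in% names(tracks)) "y" else "y_px"
  per <- list(); allsteps <- list()
  dropped <- 0L
  for (id in unique(tracks[[id_col]])) {
    tr <- tracks[tracks[[id_col]] == id, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 3) { dropped <- dropped + 1L; next }
    dx <- diff(tr[[x_col]]); dy <- diff(tr[[y_col]])
    len <- sqrt(dx^2 + dy^2)
    ok <- len >= min_step_px
    # steps ending in a border reflection carry no usable heading
    if ("reflected" %in% names(tr)) ok <- ok & !tr$reflected[-1]
    phi <- rad2deg(atan2(dy, dx))
    # angular displacement between consecutive valid steps
    vidx <- which(ok)
    if (length(vidx) < min_steps + 1) { dropped <- dropped + 1L; next }
    dphi <- wrap_deg(diff(phi[vidx]))
    dt_step <- diff(tr$frame[vidx + 1]) * dt_s
    seg_len_um <- len[vidx][-1] * pitch_um
    end_frames <- tr$frame[vidx + 1]
    # drop heading changes whose span contains a reflection event
    if ("reflected" %in% names(tr) && any(tr$reflected)) {
      rf <- tr$frame[tr$reflected]
      keep <- vapply(seq_along(dphi), function(j)
        !any(rf > end_frames[j] & rf <= end_frames[j + 1]), logical(1))
      dphi <- dphi[keep]; dt_step <- dt_step[keep]
      seg_len_um <- seg_len_um[keep]; end_frames <- end_frames[-1][keep]
      if (length(dphi) < min_steps) { dropped <- dropped + 1L; next }
    } else end_frames <- end_frames[-1]
    time_min <- sum(dt_step) / 60
    per[[length(per) + 1]] <- data.frame(
      track = id, n_steps = length(dphi),
      mean_angular_velocity_deg_min = sum(dphi) / time_min,
      curvature_rad_mm = mean(deg2rad(dphi) / (seg_len_um * 1e-3)),
      speed_um_min = sum(len * pitch_um) / (sum(diff(tr$frame)) * dt_s / 60))
    allsteps[[length(allsteps) + 1]] <- data.frame(
      track = id, step = seq_along(dphi), dphi_deg = dphi,
      cum_deg = cumsum(dphi), t_s = end_frames * dt_s)
  }
  per_track <- do.call(rbind, per)
  steps <- do.call(rbind, allsteps)
  summary <- NULL
  if (!is.null(per_track) && nrow(per_track) > 0) {
    s <- function(v) c(mean = mean(v), sd = stats::sd(v),
                       sem = stats::sd(v) / sqrt(length(v)))
    summary <- rbind(
      angular_velocity_deg_min = s(per_track$mean_angular_velocity_deg_min),
      curvature_rad_mm = s(per_track$curvature_rad_mm),
      speed_um_min = s(per_track$speed_um_min))
  }
  list(per_track = per_track, steps = steps, summary = summary,
       n_tracks = if (is.null(per_track)) 0L else nrow(per_track),
       n_dropped = dropped)
}

#' Flag cell-cell contact per frame and particle
#'
#' A particle is "in contact" when its mask, dilated by `dilate_px`,
#' intersects any other particle's mask.
#'
#' @param segmented list of per-frame [segment_cells()] results.
#' @param dilate_px dilation radius in pixels (default 2).
#' @return Data frame: `frame`, `label`, `contact`.
#' @export
contact_state <- function(segmented, dilate_px = 2) {
  brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
  out <- list()
  for (t in seq_along(segmented)) {
    lab <- segmented[[t]]$labels
    ids <- sort(unique(lab[lab > 0]))
    contact <- logical(length(ids))
    for (i in seq_along(ids)) {
      m <- EBImage::dilate(EBImage::Image((lab == ids[i]) * 1), brush)
      contact[i] <- any(EBImage::imageData(m) > 0 & lab > 0 & lab != ids[i])
    }
    out[[t]] <- data.frame(frame = t, label = ids, contact = contact)
  }
  do.call(rbind, out)
}
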