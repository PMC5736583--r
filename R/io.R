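#' Movie input/output and pipeline presets
#'
#' Movies are plain numeric arrays in display convention (`[x, y, t]` for
#' 2D, `[x, y, z, t]` for 3D) with `pitch_nm` and `dt_s` attributes. TIFF
#' pages are stored row-major (`[y, x]`); reading and writing transposes
#' accordingly. Every written image gets a JSON sidecar recording the
#' metadata and (for pipeline runs) the full configuration, because the
#' chirality sign conventions depend on the coordinate conventions.
#'
#' @name cli_io
NULL

#' Read a TIFF movie
#'
#' @param paths one path (single multi-page file) or a character vector of
#'   serially numbered files. With `layout = "2d"`, pages of one file are
#'   time frames. With `layout = "3d"`, each file is one time point whose
#'   pages are Z planes (a single 3D file yields one frame).
#' @param layout `"2d"` or `"3d"`.
#' @param pitch_nm pixel/voxel pitch metadata (length 2 or 3); required
#'   for physical-unit analyses.
#' @param dt_s frame interval metadata (seconds).
#' @return Array `[x, y, t]` or `[x, y, z, t]` with attributes `pitch_nm`
#'   and `dt_s`.
#' @export
read_movie <- function(paths, layout = c("2d", "3d"), pitch_nm = NULL,
                       dt_s = NULL) {
  layout <- match.arg(layout)
  read_pages <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) {
      if (length(dim(m)) == 3) m <- m[, , 1]  # drop extra channels
      t(m)  # [y, x] -> [x, y]
    })
  }
  if (layout == "2d") {
    if (length(paths) != 1) stop("2d layout expects a single multi-page file")
    pl <- read_pages(paths[1])
    d <- dim(pl[[1]])
    if (!all(vapply(pl, function(m) all(dim(m) == d), logical(1))))
      stop("inconsistent page shapes")
    mov <- array(unlist(pl), c(d, length(pl)))
  } else {
    stacks <- lapply(paths, read_pages)
    nz <- length(stacks[[1]])
    d <- dim(stacks[[1]][[1]])
    ok <- vapply(stacks, function(s) length(s) == nz &&
                   all(vapply(s, function(m) all(dim(m) == d), logical(1))),
                 logical(1))
    if (!all(ok)) stop("inconsistent page shapes across files")
    mov <- array(unlist(stacks), c(d, nz, length(stacks)))
  }
  sc <- find_sidecar(paths[1])
  if (!is.null(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$value_range) && diff(range(meta$value_range)) > 0)
      mov <- mov * (meta$value_range[2] - meta$value_range[1]) +
        meta$value_range[1]
    if (is.null(pitch_nm) && !is.null(meta$pitch_nm))
      pitch_nm <- meta$pitch_nm
    if (is.null(dt_s) && !is.null(meta$dt_s)) dt_s <- meta$dt_s
  }
  attr(mov, "pitch_nm") <- pitch_nm
  attr(mov, "dt_s") <- dt_s
  mov
}

#' Write a movie as 32-bit TIFF with a JSON sidecar
#'
#' Values are range-normalized and stored as 32-bit samples (relative
#' quantization 2^-32, far below physical noise); the original value range
#' is recorded in the JSON sidecar so [read_movie()] restores it.
#'
#' @param movie `[x, y, t]` or `[x, y, z, t]` array. 3D movies are written
#'   as one multi-page file per time point (`basename_t###.tif`), 2D
#'   movies as a single multi-page file.
#' @param path output path (for 3D movies, used as the basename).
#' @param sidecar additional metadata stored in the JSON sidecar.
#' @return Invisibly, the written file paths.
#' @export
write_movie <- function(movie, path, sidecar = list()) {
  d <- dim(movie)
  rng <- range(movie)
  scaled <- if (rng[2] > rng[1])
    (movie - rng[1]) / (rng[2] - rng[1]) else array(0, d)
  write_stack <- function(planes, p) {
    tiff::writeTIFF(lapply(planes, t), p, bits.per.sample = 32,
                    reduce = FALSE)
    p
  }
  if (length(d) == 3) {
    files <- write_stack(lapply(seq_len(d[3]), function(k) scaled[, , k]),
                         path)
  } else if (length(d) == 4) {
    base <- sub("\\.tiff?$", "", path)
    files <- vapply(seq_len(d[4]), function(t) {
      write_stack(lapply(seq_len(d[3]), function(z) scaled[, , z, t]),
                  sprintf("%s_t%03d.tif", base, t))
    }, character(1))
  } else stop("movie must be a 3D or 4D array")
  meta <- c(list(dim = d, value_range = rng,
                 pitch_nm = attr(movie, "pitch_nm"),
                 dt_s = attr(movie, "dt_s"),
                 axes = "x right, y down, z away from viewer (right-handed)",
                 chirality = "positive = clockwise on screen / right-screw"),
            sidecar)
  jsonlite::write_json(meta, paste0(sub("\\.tiff?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(files)
}

# Locate the JSON sidecar written next to a movie file, if any.
find_sidecar <- function(path) {
  cands <- unique(c(sub("\\.tiff?$", ".json", path),
                    sub("_t[0-9]+\\.tiff?$", ".json", path)))
  cands <- cands[file.exists(cands)]
  if (length(cands) > 0) cands[1] else NULL
}

pipeline_defaults <- function() {
  list(
    preset = "2d_migration",        # or "3d_growth_cone"
    seed = 1,
    pitch_nm = NULL, dt_s = NULL,
    shear_deg = 45, hp_sigma = 0.01, threshold = TRUE, pad = "mirror",
    expand = TRUE, drift = FALSE, zcorrect = FALSE,
    smooth = c(sx = 1, sy = 1, st = 1),
    z_upsample = 4,
    sigma_in = 1, sigma_out = 3,
    flow_alpha = 0.2, flow_iters = 300, flow_tol = 1e-5, flow_levels = NULL,
    tau_v = 0.2, tau_i = 0.1,
    seg_sigma = 2, seg_h = 0.1, gate_px = NULL, min_step_px = 0.5,
    out_dir = NULL)
}

validate_config <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

#' Run a pipeline preset over a movie
#'
#' Composes the package stages in the standard order. Preset
#' `"2d_migration"`: RT-DIC conversion, spatiotemporal smoothing,
#' watershed segmentation, flow-assisted tracking, chirality statistics.
#' Preset `"3d_growth_cone"`: range expansion, optional drift/Z
#' correction, RT-DIC conversion, smoothing, isotropic resampling,
#' structure tensor at the center frame, five-frame flow, kinematics, and
#' the local-axis projections.
#'
#' @param movie input movie array (with `pitch_nm`/`dt_s` attributes or
#'   given in `config`).
#' @param config named list overriding the defaults; unknown keys are
#'   rejected.
#' @return List of stage outputs (contents depend on the preset) plus the
#'   fully-resolved `config`. When `config$out_dir` is set, tracks/summary
#'   CSV and JSON artifacts are written there.
#' @export
run_pipeline <- function(movie, config = list()) {
  cfg <- validate_config(config)
  pitch_nm <- attr(movie, "pitch_nm")
  if (!is.null(cfg$pitch_nm)) pitch_nm <- cfg$pitch_nm
  dt_s <- attr(movie, "dt_s")
  if (!is.null(cfg$dt_s)) dt_s <- cfg$dt_s
  if (is.null(pitch_nm) || is.null(dt_s))
    stop("pitch_nm and dt_s must be supplied via attributes or config")
  out <- list(config = cfg)
  if (cfg$preset == "2d_migration") {
    if (length(dim(movie)) != 3) stop("2d_migration expects [x, y, t]")
    conv <- rtdic_convert(movie, cfg$shear_deg, cfg$hp_sigma,
                          cfg$threshold, cfg$pad)
    sm <- smooth_spatiotemporal(conv, cfg$smooth[["sx"]], cfg$smooth[["sy"]],
                                cfg$smooth[["st"]])
    nt <- dim(movie)[3]
    seg <- lapply(seq_len(nt), function(k)
      segment_cells(sm[, , k], cfg$seg_sigma, cfg$seg_h))
    flows <- lapply(seq_len(nt - 1), function(k)
      pyramid_flow(sm[, , k], sm[, , k + 1], levels = cfg$flow_levels,
                   alpha = cfg$flow_alpha, n_iter = cfg$flow_iters,
                   tol = cfg$flow_tol))
    tracks <- link_tracks(seg, flows, gate_px = cfg$gate_px)
    stats <- chirality_stats(tracks, dt_s, pitch_nm[1] / 1000,
                             min_step_px = cfg$min_step_px)
    out <- c(out, list(converted = conv, segmented = seg, tracks = tracks,
                       chirality = stats))
  } else if (cfg$preset == "3d_growth_cone") {
    if (length(dim(movie)) != 4) stop("3d_growth_cone expects [x, y, z, t]")
    mov <- movie
    if (cfg$expand) mov <- expand_range(mov)
    if (cfg$drift) mov <- correct_xy_drift(mov)
    if (cfg$zcorrect)
      for (t in seq_len(dim(mov)[4]))
        mov[, , , t] <- correct_z_positions(mov[, , , t])
    conv <- rtdic_convert(mov, cfg$shear_deg, cfg$hp_sigma,
                          cfg$threshold, cfg$pad)
    conv <- smooth_spatiotemporal(conv, cfg$smooth[["sx"]],
                                  cfg$smooth[["sy"]], cfg$smooth[["st"]])
    if (pitch_nm[3] > pitch_nm[1]) {
      attr(conv, "pitch_nm") <- pitch_nm
      conv <- resample_isotropic(conv, cfg$z_upsample)
      pitch_nm <- attr(conv, "pitch_nm")
    }
    conv <- conv / max(conv)
    nt <- dim(conv)[4]
    if (nt < 5) stop("need at least 5 frames for kinematics")
    tmid <- (nt + 1) %/% 2
    tmid <- min(max(tmid, 3), nt - 2)
    tf <- certainties(compute_tensor(conv[, , , tmid], cfg$sigma_in,
                                     cfg$sigma_out))
    fs <- five_frame_flowset(conv[, , , (tmid - 2):(tmid + 2)],
                             levels = cfg$flow_levels,
                             alpha = cfg$flow_alpha,
                             n_iter = cfg$flow_iters, tol = cfg$flow_tol)
    kin <- derive_kinematics(fs, dt_s, pitch_nm / 1000,
                             tau_v = cfg$tau_v, tau_i = cfg$tau_i)
    ctr_int <- conv[, , , tmid]
    d3 <- dim(ctr_int)
    coords <- as.matrix(expand.grid(lapply(d3, seq_len)))
    centroid <- unname(colSums(coords * as.vector(ctr_int)) / sum(ctr_int))
    dirf <- orient_to_tip(tf, centroid)
    proj <- local_axis_projection(kin, dirf)
    radial <- radial_axis_projection(kin, ctr_int, tf$Ct)
    out <- c(out, list(converted = conv, tensor = tf, kinematics = kin,
                       local = proj, radial = radial,
                       center_frame = tmid))
  } else stop("unknown preset: ", cfg$preset)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config = cfg[!vapply(cfg, is.null, logical(1))],
           pitch_nm = pitch_nm, dt_s = dt_s,
           axes = "x right, y down, z away from viewer (right-handed)"),
      file.path(cfg$out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(out$tracks))
      utils::write.csv(out$tracks, file.path(cfg$out_dir, "tracks.csv"),
                       row.names = FALSE)
    if (!is.null(out$chirality) && !is.null(out$chirality$per_track))
      utils::write.csv(out$chirality$per_track,
                       file.path(cfg$out_dir, "per_track.csv"),
                       row.names = FALSE)
  }
  out
}
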