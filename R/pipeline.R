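# Project-level orchestration: standardized session layout, JSON config
# with strict key validation, per-stage logging, idempotent batch runs.

stage_dirs <- c(calibration = "calibration", pose2d = "pose-2d",
                filtered = "pose-2d-filtered", pose3d = "pose-3d",
                angles = "angles")

#' Default project configuration
#'
#' All tunable parameters of the pipeline with their defaults; a project
#' config file may override any subset, and unknown keys are rejected.
#'
#' @return Nested list.
#' @export
default_config <- function() {
  list(
    project = list(nesting = 1L, seed = 1L, camera_regex = "(cam[0-9]+)"),
    calibration = list(
      board = list(squares_x = 6L, squares_y = 6L, square_size = 0.5,
                   marker_size = 0.375),
      n_iter = 12L, mu_start = 15, mu_end = 1, loss = "linear",
      max_frames = 100L
    ),
    filter = list(
      type = "viterbi", # one of median, viterbi, autoencoder, viterbi+autoencoder
      medfilt_window = 13L, offset_threshold = 20, spline = TRUE,
      viterbi_sigma = 10, viterbi_max_gap = 5L, dedup_radius = 7,
      autoencoder_drop = 0.5, autoencoder_epochs = 30L
    ),
    triangulation = list(
      method = "regularized", # linear, ransac, regularized
      beta_time = 2, alpha_limb = 2, derivative_order = 2L,
      robust_norm = "huber", robust_scale = 10, reproj_drop = 20,
      chunk_size = 500L, chunk_overlap = 50L
    ),
    angles = list(body_frame = c("origin", "head", "dorsum")),
    skeleton = list(joints = list(), limbs = list(), chains = list()),
    cameras = list(image_size = c(832L, 632L)),
    frame_rate = 300
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- paste0(path, if (nzchar(path)) "." else "", nm)
    if (!nm %in% names(base)) {
      abort(sprintf("unknown configuration key: '%s'", here))
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a project configuration
#'
#' Reads `config.json` at the project root (when present), overlays it
#' on [default_config()], and rejects unknown keys.
#'
#' @param root Project root directory.
#' @return The materialized config list.
#' @export
load_config <- function(root) {
  path <- file.path(root, "config.json")
  cfg <- default_config()
  if (file.exists(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, user)
  }
  cfg
}

# JSON round trips can deliver the skeleton block as lists, data frames
# or matrices (jsonlite simplifies equal-length arrays); accept all.
config_skeleton <- function(cfg) {
  sk <- cfg$skeleton
  if (!length(sk$joints)) return(NULL)
  lb <- sk$limbs
  limbs <- if (is.data.frame(lb)) {
    tibble(joint_a = as.character(lb$joint_a),
           joint_b = as.character(lb$joint_b),
           weight = if ("weight" %in% names(lb)) as.numeric(lb$weight) else 1)
  } else if (is.matrix(lb)) {
    tibble(joint_a = as.character(lb[, 1]), joint_b = as.character(lb[, 2]),
           weight = if (ncol(lb) >= 3) as.numeric(lb[, 3]) else 1)
  } else if (length(lb)) {
    purrr::map_dfr(lb, function(l) {
      l <- as.list(l)
      tibble(joint_a = as.character(l[[1]]), joint_b = as.character(l[[2]]),
             weight = if (length(l) >= 3) as.numeric(l[[3]]) else 1)
    })
  } else NULL
  ch <- sk$chains
  chains <- if (is.matrix(ch)) {
    lapply(seq_len(nrow(ch)), function(i) as.character(ch[i, ]))
  } else {
    lapply(ch, function(x) as.character(unlist(x)))
  }
  skeleton(as.character(unlist(sk$joints)), limbs, chains)
}

skeleton_to_config <- function(skel) {
  list(
    joints = as.list(skel$joints),
    limbs = lapply(seq_len(nrow(skel$limbs)), function(i) {
      list(joint_a = skel$limbs$joint_a[i], joint_b = skel$limbs$joint_b[i],
           weight = skel$limbs$weight[i])
    }),
    chains = lapply(skel$chains, as.list)
  )
}

#' Discover sessions in a project
#'
#' Sessions are directories at the configured nesting depth below the
#' project root, returned in lexicographic order. A session is any
#' directory that contains (or will receive) the per-stage slots
#' `calibration/`, `pose-2d/`, `pose-2d-filtered/`, `pose-3d/`,
#' `angles/`.
#'
#' @param root Project root.
#' @param config Optional config (for the nesting depth).
#' @return Character vector of session paths.
#' @export
discover_sessions <- function(root, config = NULL) {
  if (!dir.exists(root)) abort(sprintf("project root '%s' does not exist", root))
  config <- config %||% load_config(root)
  depth <- config$project$nesting
  dirs <- root
  for (d in seq_len(depth)) {
    dirs <- unlist(lapply(dirs, function(p) {
      list.dirs(p, recursive = FALSE)
    }))
    dirs <- dirs[order(basename(dirs))]
  }
  keep <- vapply(dirs, function(p) {
    any(dir.exists(file.path(p, stage_dirs))) ||
      length(list.files(p)) == 0
  }, TRUE)
  sessions <- dirs[keep]
  if (!length(sessions)) abort("no sessions found in project")
  sessions
}

freeze_config <- function(cfg, dir) {
  jsonlite::write_json(cfg, file.path(dir, "config.frozen.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = I(17))
}

log_line <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  cat(msg, "\n", file = log_path, append = TRUE)
  invisible(msg)
}

outputs_current <- function(outputs, inputs) {
  if (!all(file.exists(outputs))) return(FALSE)
  if (!length(inputs)) return(TRUE)
  min(file.mtime(outputs)) >= max(file.mtime(inputs))
}

read_stage_tables <- function(dir, camera_regex) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) return(NULL)
  purrr::map_dfr(files, function(f) {
    d <- as_tibble(utils::read.csv(f, stringsAsFactors = FALSE))
    if (!"camera" %in% names(d)) {
      m <- regmatches(basename(f), regexpr(camera_regex, basename(f)))
      if (!length(m)) abort(sprintf("cannot infer camera from '%s'", f))
      d$camera <- m
    }
    d
  })
}

#' Run one pipeline stage over all sessions
#'
#' Stages: `calibrate` (board detections -> calibration file), `filter`
#' (pose-2d -> pose-2d-filtered), `triangulate` (filtered 2D +
#' calibration -> pose-3d), `angles` (pose-3d -> angle tables). Each
#' stage checks that its upstream outputs exist, skips sessions whose
#' outputs are already current unless `force`, freezes the config next
#' to its outputs, and appends to a per-session log.
#'
#' @param root Project root.
#' @param stage One of `"calibrate"`, `"filter"`, `"triangulate"`,
#'   `"angles"`.
#' @param config Optional pre-loaded config.
#' @param force Recompute even when outputs are current.
#' @param verbose Echo log lines to the console.
#' @return Tibble of per-session outcomes, invisibly.
#' @export
run_stage <- function(root, stage = c("calibrate", "filter", "triangulate",
                                      "angles"),
                      config = NULL, force = FALSE, verbose = FALSE) {
  stage <- match.arg(stage)
  config <- config %||% load_config(root)
  sessions <- discover_sessions(root, config)
  res <- purrr::map_dfr(sessions, function(s) {
    t0 <- Sys.time()
    log_dir <- file.path(s, "logs")
    dir.create(log_dir, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(log_dir, paste0(stage, ".log"))
    status <- run_stage_session(s, stage, config, force, log_path)
    if (verbose) message(sprintf("%s: %s [%s, %.2fs]", basename(s), stage,
                                 status,
                                 as.numeric(Sys.time() - t0, units = "secs")))
    tibble(session = s, stage = stage, status = status,
           seconds = as.numeric(Sys.time() - t0, units = "secs"))
  })
  invisible(res)
}

run_stage_session <- function(s, stage, config, force, log_path) {
  regex <- config$project$camera_regex
  seed <- config$project$seed
  if (stage == "calibrate") {
    in_file <- file.path(s, "calibration", "board_detections.csv")
    if (!file.exists(in_file)) {
      abort(sprintf("session '%s': missing calibration detections (run the detector/simulate first)", s))
    }
    out_file <- file.path(s, "calibration", "calibration.json")
    if (!force && outputs_current(out_file, in_file)) return("skipped")
    det <- as_tibble(utils::read.csv(in_file, stringsAsFactors = FALSE))
    bc <- config$calibration$board
    board <- board_geometry(bc$squares_x, bc$squares_y, bc$square_size,
                            bc$marker_size)
    sizes <- lapply(setNames(unique(det$camera), unique(det$camera)),
                    function(cm) config$cameras$image_size)
    cal <- calibrate_cameras(det, board, sizes,
                             n_iter = config$calibration$n_iter,
                             mu_start = config$calibration$mu_start,
                             mu_end = config$calibration$mu_end,
                             loss = config$calibration$loss,
                             max_frames = config$calibration$max_frames,
                             seed = seed)
    write_calibration(cal$rig, out_file)
    freeze_config(config, file.path(s, "calibration"))
    log_line(log_path, "calibrated %d cameras, mean reprojection %.3f px, seed %d",
             length(cal$rig), cal$summary$mean_error, seed)
    return("done")
  }

  if (stage == "filter") {
    in_dir <- file.path(s, stage_dirs["pose2d"])
    if (!dir.exists(in_dir) || !length(list.files(in_dir, pattern = "\\.csv$"))) {
      abort(sprintf("session '%s': missing pose-2d outputs; run the detector stage first", s))
    }
    out_dir <- file.path(s, stage_dirs["filtered"])
    dir.create(out_dir, showWarnings = FALSE)
    out_file <- file.path(out_dir, "keypoints.csv")
    inputs <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
    if (!force && outputs_current(out_file, inputs)) return("skipped")
    cand <- read_stage_tables(in_dir, regex)
    fcfg <- config$filter
    types <- strsplit(fcfg$type, "+", fixed = TRUE)[[1]]
    series <- cand
    for (tp in types) {
      series <- switch(
        tp,
        median = filter_keypoints_median(series, fcfg$medfilt_window,
                                         fcfg$offset_threshold, fcfg$spline),
        viterbi = filter_keypoints_viterbi(series, fcfg$viterbi_sigma,
                                           fcfg$viterbi_max_gap,
                                           fcfg$dedup_radius),
        autoencoder = {
          joints <- sort(unique(series$joint))
          tr <- simulate_score_vectors(length(joints), 20000L,
                                       seed = sub_seed(seed, "ae-data"))
          model <- fit_score_autoencoder(tr$scores, tr$visible,
                                         epochs = fcfg$autoencoder_epochs,
                                         seed = sub_seed(seed, "ae-fit"))
          filter_keypoints_autoencoder(series, model, fcfg$autoencoder_drop)
        },
        abort(sprintf("unknown filter type '%s'", tp))
      )
    }
    utils::write.csv(series, out_file, row.names = FALSE)
    freeze_config(config, out_dir)
    log_line(log_path, "filtered with %s, %d rows, seed %d", fcfg$type,
             nrow(series), seed)
    return("done")
  }

  if (stage == "triangulate") {
    cal_file <- file.path(s, "calibration", "calibration.json")
    if (!file.exists(cal_file)) {
      abort(sprintf("session '%s': missing calibration; run 'calibrate' first", s))
    }
    in_file <- file.path(s, stage_dirs["filtered"], "keypoints.csv")
    if (!file.exists(in_file)) {
      abort(sprintf("session '%s': missing filtered keypoints; run 'filter' first", s))
    }
    out_dir <- file.path(s, stage_dirs["pose3d"])
    dir.create(out_dir, showWarnings = FALSE)
    out_file <- file.path(out_dir, "points3d.csv")
    if (!force && outputs_current(out_file, c(cal_file, in_file))) {
      return("skipped")
    }
    rig <- read_calibration(cal_file)
    series <- as_tibble(utils::read.csv(in_file, stringsAsFactors = FALSE))
    tc <- config$triangulation
    if (tc$method == "regularized") {
      skel <- config_skeleton(config)
      if (is.null(skel)) abort("regularized triangulation needs a skeleton in the config")
      fit <- triangulate_regularized(series, rig, skel,
                                     beta_time = tc$beta_time,
                                     alpha_limb = tc$alpha_limb,
                                     derivative_order = tc$derivative_order,
                                     robust_norm = tc$robust_norm,
                                     robust_scale = tc$robust_scale,
                                     reproj_drop = tc$reproj_drop,
                                     chunk_size = tc$chunk_size,
                                     chunk_overlap = tc$chunk_overlap,
                                     frame_rate = config$frame_rate)
      traj <- fit$traj
      utils::write.csv(fit$limb_lengths,
                       file.path(out_dir, "limb_lengths.csv"),
                       row.names = FALSE)
    } else {
      traj <- triangulate_points(series, rig, method = tc$method)
    }
    utils::write.csv(traj, out_file, row.names = FALSE)
    freeze_config(config, out_dir)
    log_line(log_path, "triangulated (%s), %d points", tc$method, nrow(traj))
    return("done")
  }

  if (stage == "angles") {
    in_file <- file.path(s, stage_dirs["pose3d"], "points3d.csv")
    if (!file.exists(in_file)) {
      abort(sprintf("session '%s': missing 3D points; run 'triangulate' first", s))
    }
    out_dir <- file.path(s, stage_dirs["angles"])
    dir.create(out_dir, showWarnings = FALSE)
    out_file <- file.path(out_dir, "angles.csv")
    if (!force && outputs_current(out_file, in_file)) return("skipped")
    traj <- as_tibble(utils::read.csv(in_file, stringsAsFactors = FALSE))
    skel <- config_skeleton(config)
    if (is.null(skel) || !length(skel$chains)) {
      abort("angle extraction needs skeleton chains in the config")
    }
    bf <- config$angles$body_frame
    ang <- purrr::map_dfr(skel$chains, function(ch) {
      chain_angles(traj, ch, body_frame = bf)
    })
    utils::write.csv(ang, out_file, row.names = FALSE)
    freeze_config(config, out_dir)
    log_line(log_path, "extracted %d angle samples over %d chains",
             nrow(ang), length(skel$chains))
    return("done")
  }
  abort("unreachable")
}

#' Create a complete synthetic project on disk
#'
#' Writes a project with one session containing calibration board
#' detections, multi-candidate 2D keypoint detections of a rigid
#' articulated walker, ground-truth 3D positions, and a config wired to
#' the generating skeleton — everything the pipeline stages need.
#'
#' @param root Directory to create.
#' @param n_cameras,n_board_frames,n_frames Scene sizes.
#' @param noise_px Detection noise for the walker keypoints (pixels).
#' @param board_noise_px Detection noise for board corners.
#' @param outlier_frac Teleporting-outlier fraction for keypoints.
#' @param seed Project seed.
#' @return The project root, invisibly.
#' @export
simulate_project <- function(root, n_cameras = 6L, n_board_frames = 150L,
                             n_frames = 120L, noise_px = 2,
                             board_noise_px = 0.5, outlier_frac = 0.05,
                             seed = 1L) {
  skel <- example_skeleton(2L)
  cfg <- default_config()
  cfg$project$seed <- seed
  cfg$skeleton <- skeleton_to_config(skel)
  cfg$filter$type <- "viterbi"
  session <- file.path(root, "session1")
  for (d in stage_dirs) dir.create(file.path(session, d), recursive = TRUE,
                                   showWarnings = FALSE)
  jsonlite::write_json(cfg, file.path(root, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = I(17))

  rig <- simulate_rig(n_cameras, seed = seed)
  board <- board_geometry()
  bs <- simulate_board_sequence(rig, board, n_frames = n_board_frames,
                                noise_px = board_noise_px,
                                seed = sub_seed(seed, "project-board"))
  utils::write.csv(bs$detections[, c("camera", "frame", "corner_id", "x", "y")],
                   file.path(session, "calibration", "board_detections.csv"),
                   row.names = FALSE)
  traj <- simulate_articulated_walker(skel, n_frames = n_frames,
                                      frame_rate = cfg$frame_rate,
                                      seed = sub_seed(seed, "project-walker"))
  cand <- simulate_detections(traj, rig, noise_px = noise_px,
                              outlier_frac = outlier_frac,
                              seed = sub_seed(seed, "project-detect"))
  for (cm in unique(cand$camera)) {
    utils::write.csv(cand[cand$camera == cm, ],
                     file.path(session, "pose-2d", paste0(cm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(traj, file.path(session, "ground_truth_3d.csv"),
                   row.names = FALSE)
  invisible(root)
}

#' Run the full pipeline on a project
#'
#' @param root Project root.
#' @param force Recompute all stages.
#' @param verbose Echo progress.
#' @return Tibble of stage outcomes.
#' @export
run_pipeline <- function(root, force = FALSE, verbose = FALSE) {
  cfg <- load_config(root)
  out <- purrr::map_dfr(c("calibrate", "filter", "triangulate", "angles"),
                        function(st) {
    run_stage(root, st, config = cfg, force = force, verbose = verbose)
  })
  out
}
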