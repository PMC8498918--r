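# Filtering of per-camera 2D keypoint detections.

#' Median filter for 2D keypoint series
#'
#' Compares each joint's raw trajectory to its rolling median (per
#' coordinate); points deviating more than `offset_threshold` pixels
#' (Euclidean) are treated as outliers and removed, then gaps up to
#' `max_gap` frames (including pre-existing missing data) are
#' interpolated with a cubic spline (or linearly).
#'
#' @param series Tibble (camera, frame, joint, x, y, score).
#' @param window Odd rolling-median window length (frames), >= 3.
#' @param offset_threshold Outlier distance threshold in pixels.
#' @param spline Use cubic-spline interpolation (`TRUE`) or linear.
#' @param max_gap Longest gap (frames) to interpolate; defaults to
#'   `window`. Interpolated points get score 0.
#' @return Filtered series tibble with the same columns.
#' @export
filter_keypoints_median <- function(series, window = 13L,
                                    offset_threshold = 20,
                                    spline = TRUE, max_gap = window) {
  if (window < 3 || window %% 2 != 1) abort("window must be odd and >= 3")
  if (!"score" %in% names(series)) series$score <- 1
  method <- if (spline) "spline" else "linear"
  series |>
    dplyr::group_by(.data$camera, .data$joint) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      mx <- rolling_median(df$x, window)
      my <- rolling_median(df$y, window)
      dev <- sqrt((df$x - mx)^2 + (df$y - my)^2)
      out <- !is.na(dev) & dev > offset_threshold
      x <- df$x; y <- df$y; s <- df$score
      x[out] <- NA_real_; y[out] <- NA_real_
      was_na <- is.na(x)
      x <- interp_gaps(x, max_gap = max_gap, method = method)
      y <- interp_gaps(y, max_gap = max_gap, method = method)
      s[was_na] <- 0
      s[is.na(x)] <- 0
      df$x <- x; df$y <- y; df$score <- s
      df
    }) |>
    dplyr::ungroup()
}

# exact Viterbi decode for one joint in one camera.
# candidates: tibble(frame, x, y, score) possibly several rows per frame.
viterbi_decode_joint <- function(cand, frames, sigma, max_gap,
                                 dedup_radius = 7, score_floor = 1e-6) {
  # deduplicate within each frame: keep the highest-score candidate of
  # any cluster of detections closer than dedup_radius
  cand <- cand[order(cand$frame, -cand$score), ]
  kept <- logical(nrow(cand))
  for (fr in unique(cand$frame)) {
    idx <- which(cand$frame == fr)
    acc <- integer(0)
    for (i in idx) {
      if (!length(acc)) { kept[i] <- TRUE; acc <- i; next }
      d2 <- (cand$x[acc] - cand$x[i])^2 + (cand$y[acc] - cand$y[i])^2
      if (all(d2 > dedup_radius^2)) { kept[i] <- TRUE; acc <- c(acc, i) }
    }
  }
  cand <- cand[kept, ]

  TT <- length(frames)
  # state list per frame: fresh candidates + carryovers up to max_gap
  states <- vector("list", TT)
  for (t in seq_len(TT)) {
    fresh <- cand[cand$frame == frames[t], ]
    st <- NULL
    if (nrow(fresh)) {
      st <- tibble(x = fresh$x, y = fresh$y,
                   logscore = log(pmax(fresh$score, score_floor)),
                   fresh = TRUE)
    }
    for (g in seq_len(min(max_gap, t - 1))) {
      prev <- cand[cand$frame == frames[t - g], ]
      if (nrow(prev)) {
        st <- dplyr::bind_rows(st, tibble(
          x = prev$x, y = prev$y,
          logscore = log(pmax(prev$score, score_floor)) - g * log(2),
          fresh = FALSE
        ))
      }
    }
    states[[t]] <- st
  }

  log_trans <- function(s_from, s_to, sigma) {
    d2 <- outer(s_from$x, s_to$x, `-`)^2 + outer(s_from$y, s_to$y, `-`)^2
    lt <- -d2 / (2 * sigma^2)
    lt[d2 > (6 * sigma)^2] <- -Inf # truncated to keep the trellis sparse
    lt
  }

  delta <- vector("list", TT)
  back <- vector("list", TT)
  for (t in seq_len(TT)) {
    st <- states[[t]]
    if (is.null(st) || !nrow(st)) { delta[[t]] <- NULL; next }
    if (t == 1 || is.null(delta[[t - 1]])) {
      delta[[t]] <- st$logscore
      back[[t]] <- rep(NA_integer_, nrow(st))
      next
    }
    prev <- states[[t - 1]]
    lt <- log_trans(prev, st, sigma)
    scores <- delta[[t - 1]] + lt # matrix prev x cur
    best_prev <- apply(scores, 2, which.max)
    best_val <- scores[cbind(best_prev, seq_len(nrow(st)))]
    if (all(!is.finite(best_val))) { # path broken: restart
      delta[[t]] <- st$logscore
      back[[t]] <- rep(NA_integer_, nrow(st))
    } else {
      delta[[t]] <- best_val + st$logscore
      back[[t]] <- best_prev
    }
  }

  # backtrack segment by segment (a segment starts wherever the path had
  # to restart because no transition was feasible)
  out <- tibble(frame = frames, x = NA_real_, y = NA_real_,
                score = NA_real_)
  has_delta <- !vapply(delta, is.null, TRUE)
  t_cur <- if (any(has_delta)) max(which(has_delta)) else 0L
  while (t_cur >= 1) {
    s <- which.max(delta[[t_cur]])
    repeat {
      st <- states[[t_cur]]
      if (st$fresh[s]) {
        out$x[t_cur] <- st$x[s]; out$y[t_cur] <- st$y[s]
        out$score[t_cur] <- exp(st$logscore[s])
      }
      p <- back[[t_cur]][s]
      if (is.na(p)) break # reached the start of this segment
      t_cur <- t_cur - 1L
      s <- p
    }
    t_cur <- t_cur - 1L
    while (t_cur >= 1 && !has_delta[t_cur]) t_cur <- t_cur - 1L
  }
  out
}

#' Viterbi filter for multi-candidate keypoint detections
#'
#' Per joint and camera, candidate detections in each frame are the
#' states of a hidden Markov model: emission weight is the detection
#' confidence, transition weight an isotropic Gaussian on the
#' displacement with standard deviation `sigma`. Duplicate detections
#' within `dedup_radius` pixels are merged, and candidates from up to
#' `max_gap` previous frames are carried forward with score multiplied
#' by `2^-gap` to bridge missed detections. The single
#' maximum-probability path is decoded exactly; frames whose selected
#' state is a carryover are reported missing.
#'
#' @param candidates Tibble (camera, frame, joint, x, y, score),
#'   possibly several candidate rows per (camera, frame, joint).
#' @param sigma Transition standard deviation in pixels.
#' @param max_gap Maximum carryover F in frames.
#' @param dedup_radius Duplicate-merge radius in pixels (default 7).
#' @return Tibble (camera, frame, joint, x, y, score), one row per
#'   (camera, frame, joint), missing coordinates where no consistent
#'   detection exists.
#' @export
filter_keypoints_viterbi <- function(candidates, sigma = 10, max_gap = 5L,
                                     dedup_radius = 7) {
  stopifnot(sigma > 0)
  cand <- candidates[is.finite(candidates$x) & is.finite(candidates$y), ]
  frames <- seq(min(candidates$frame), max(candidates$frame))
  combos <- dplyr::distinct(candidates, .data$camera, .data$joint)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    cm <- combos$camera[i]; jt <- combos$joint[i]
    sub <- cand[cand$camera == cm & cand$joint == jt,
                c("frame", "x", "y", "score")]
    res <- viterbi_decode_joint(sub, frames, sigma, max_gap, dedup_radius)
    res$camera <- cm; res$joint <- jt
    res[, c("camera", "frame", "joint", "x", "y", "score")]
  })
}
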