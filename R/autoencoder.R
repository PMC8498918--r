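# Confidence-score autoencoder: flags confidently-wrong detections of
# occluded joints by learning the joint structure of per-frame score
# vectors.

#' Generate synthetic training data for the score autoencoder
#'
#' Emulates what a keypoint detector emits: per frame, each joint is
#' visible or occluded, and its confidence score is drawn from a normal
#' distribution with standard deviation 0.3 and mean 1 (visible) or 0
#' (invisible), clipped to [0, 1]. To mimic false positives/negatives,
#' 5% of the scores are flipped (`x -> 1 - x`) at random. Visibility is
#' sampled per frame: each joint independently visible with probability
#' `p_visible`, and a fraction of frames use a structured occlusion (a
#' contiguous block of joints hidden), mimicking one body part leaving
#' the view.
#'
#' @param n_joints Number of joints per frame.
#' @param n_samples Number of frames to generate.
#' @param seed Integer seed (deterministic output).
#' @param p_visible Marginal visibility probability.
#' @param structured_frac Fraction of frames with a contiguous occlusion
#'   block.
#' @param flip_rate Fraction of scores flipped.
#' @param score_sd Standard deviation of the score distribution.
#' @return List with `scores` (n_samples x n_joints matrix) and
#'   `visible` (logical matrix of the same shape).
#' @export
simulate_score_vectors <- function(n_joints, n_samples, seed = 1L,
                                   p_visible = 0.8, structured_frac = 0.1,
                                   flip_rate = 0.05, score_sd = 0.3) {
  stopifnot(n_joints >= 1)
  set.seed(sub_seed(seed, "score-vectors"))
  visible <- matrix(runif(n_samples * n_joints) < p_visible,
                    n_samples, n_joints)
  n_struct <- round(structured_frac * n_samples)
  if (n_struct > 0 && n_joints >= 2) {
    rows <- sample(n_samples, n_struct)
    for (r in rows) {
      len <- sample(seq_len(max(1L, floor(n_joints / 2))), 1)
      start <- sample(n_joints - len + 1L, 1)
      visible[r, start:(start + len - 1L)] <- FALSE
    }
  }
  mu <- ifelse(visible, 1, 0)
  scores <- matrix(clamp(rnorm(n_samples * n_joints, mean = mu,
                               sd = score_sd), 0, 1),
                   n_samples, n_joints)
  flip <- runif(n_samples * n_joints) < flip_rate
  scores[flip] <- 1 - scores[flip]
  list(scores = scores, visible = visible)
}

#' Train the score autoencoder
#'
#' A multilayer perceptron with a single hidden layer of tanh units
#' (hidden width = number of joints) and sigmoid outputs, trained with
#' the Adam optimizer to map a frame's raw score vector to the
#' underlying visibility pattern.
#'
#' @param scores n x n_joints matrix of raw scores (training inputs).
#' @param visible n x n_joints logical/0-1 matrix (training targets).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Seed for initialization and shuffling.
#' @return An object of class `score_autoencoder`.
#' @export
fit_score_autoencoder <- function(scores, visible, epochs = 30L,
                                  batch_size = 64L, lr = 1e-2, seed = 1L) {
  X <- as.matrix(scores)
  Y <- matrix(as.numeric(visible), nrow(X), ncol(X))
  n <- nrow(X); d <- ncol(X); h <- d # hidden width = joint count
  set.seed(sub_seed(seed, "autoencoder-init"))
  W1 <- matrix(rnorm(d * h, sd = sqrt(1 / d)), d, h); b1 <- numeric(h)
  W2 <- matrix(rnorm(h * d, sd = sqrt(1 / h)), h, d); b2 <- numeric(d)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  sigmoid <- function(z) 1 / (1 + exp(-z))
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      nb <- nrow(Xb)
      H <- tanh(sweep(Xb %*% params$W1, 2, params$b1, `+`))
      P <- sigmoid(sweep(H %*% params$W2, 2, params$b2, `+`))
      # d/dz of MSE through the sigmoid
      dZ2 <- 2 * (P - Yb) * P * (1 - P) / nb
      gW2 <- t(H) %*% dZ2; gb2 <- colSums(dZ2)
      dH <- dZ2 %*% t(params$W2) * (1 - H^2)
      gW1 <- t(Xb) %*% dH; gb1 <- colSums(dH)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      step <- step + 1L
      for (nm in names(params)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^step)
        vhat <- vel[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  structure(list(params = params, n_joints = d, hidden = h),
            class = "score_autoencoder")
}

#' @export
print.score_autoencoder <- function(x, ...) {
  cat(sprintf("<score_autoencoder> %d joints, %d tanh hidden units\n",
              x$n_joints, x$hidden))
  invisible(x)
}

#' Corrected confidence scores for a matrix of raw scores
#'
#' @param object A `score_autoencoder`.
#' @param newdata n x n_joints matrix of raw scores.
#' @param ... Unused.
#' @return Matrix of corrected scores in [0, 1].
#' @export
predict.score_autoencoder <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_joints) {
    abort(sprintf("model expects %d joints, got %d", object$n_joints, ncol(X)))
  }
  p <- object$params
  H <- tanh(sweep(X %*% p$W1, 2, p$b1, `+`))
  clamp(1 / (1 + exp(-sweep(H %*% p$W2, 2, p$b2, `+`))), 0, 1)
}

#' Apply the score autoencoder to a keypoint series
#'
#' Replaces each detection's score with the corrected score for its
#' (camera, frame) score vector, and drops keypoints whose corrected
#' score falls below `drop_threshold` (their coordinates become
#' missing).
#'
#' @param series Tibble (camera, frame, joint, x, y, score), one row per
#'   (camera, frame, joint).
#' @param model A [fit_score_autoencoder()] model trained for the same
#'   joint set.
#' @param drop_threshold Corrected-score cutoff (default 0.5); use 0 to
#'   only rewrite scores.
#' @return The series with corrected scores and dropped keypoints.
#' @export
filter_keypoints_autoencoder <- function(series, model, drop_threshold = 0.5) {
  joints <- sort(unique(series$joint))
  if (length(joints) != model$n_joints) {
    abort(sprintf("series has %d joints but model expects %d",
                  length(joints), model$n_joints))
  }
  wide <- series |>
    dplyr::mutate(score_in = ifelse(is.finite(.data$score), .data$score, 0)) |>
    dplyr::select(dplyr::all_of(c("camera", "frame", "joint", "score_in"))) |>
    tidyr::pivot_wider(names_from = "joint", values_from = "score_in",
                       values_fill = 0)
  S <- as.matrix(wide[, joints, drop = FALSE])
  corrected <- predict(model, S)
  long <- wide[, c("camera", "frame")]
  colnames(corrected) <- joints
  corr_df <- as_tibble(corrected)
  long <- dplyr::bind_cols(long, corr_df) |>
    tidyr::pivot_longer(dplyr::all_of(joints), names_to = "joint",
                        values_to = "score_corrected")
  out <- dplyr::left_join(series, long, by = c("camera", "frame", "joint"))
  out$score <- out$score_corrected
  drop <- !is.na(out$score) & out$score < drop_threshold
  out$x[drop] <- NA_real_
  out$y[drop] <- NA_real_
  out$score_corrected <- NULL
  out
}
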