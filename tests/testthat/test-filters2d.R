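make_series <- function(x, y, score = 1, camera = "c", joint = "j") {
  tibble::tibble(camera = camera, frame = seq_along(x), joint = joint,
                 x = x, y = y, score = score)
}

test_that("median filter leaves smooth trajectories untouched", {
  t <- seq(0, 4 * pi, length.out = 120)
  s <- make_series(100 + 30 * sin(t), 80 + 20 * cos(t))
  out <- filter_keypoints_median(s, window = 13, offset_threshold = 20)
  expect_equal(out$x, s$x, tolerance = 1e-12)
  expect_equal(out$y, s$y, tolerance = 1e-12)
})

test_that("median filter removes a single-frame spike and interpolates it", {
  x <- seq(0, 99); y <- 0.5 * x
  x[50] <- x[50] + 80
  s <- make_series(x, y)
  out <- filter_keypoints_median(s, window = 9, offset_threshold = 20)
  # interpolated point back on the line within 1 px, score zeroed
  expect_lt(abs(out$x[50] - 49), 1)
  expect_equal(out$score[50], 0)
  expect_equal(out$x[-50], x[-50])
})

test_that("rolling median equals the brute-force sorted median", {
  set.seed(31)
  x <- rnorm(101)
  x[sample(101, 7)] <- NA
  w <- 9; half <- 4
  brute <- vapply(seq_along(x), function(i) {
    v <- x[max(1, i - half):min(length(x), i + half)]
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  }, numeric(1))
  expect_equal(mocap3d:::rolling_median(x, w), brute)
})

test_that("median filter rejects windows larger than the series", {
  s <- make_series(1:5, 1:5)
  expect_error(filter_keypoints_median(s, window = 7), "window")
  expect_error(filter_keypoints_median(s, window = 4), "odd")
})

test_that("viterbi filter is the identity on clean single-candidate data", {
  s <- make_series(seq(0, 95, by = 5), rep(10, 20))
  s$rank <- 1L
  out <- filter_keypoints_viterbi(s, sigma = 10)
  expect_equal(out$x, s$x)
  expect_equal(out$y, s$y)
})

test_that("candidates within the dedup radius are merged", {
  cand <- tibble::tibble(camera = "c", frame = rep(1:5, each = 2), joint = "j",
                         x = rep(c(10, 13), 5), y = 0,
                         score = rep(c(0.9, 0.5), 5))
  out <- filter_keypoints_viterbi(cand, sigma = 10, dedup_radius = 7)
  # the low-score near-duplicate 3 px away never wins
  expect_equal(out$x, rep(10, 5))
})

test_that("viterbi equals exhaustive path enumeration on small trellises", {
  set.seed(33)
  for (rep in 1:8) {
    n_f <- sample(2:4, 1); n_c <- sample(2:3, 1)
    cand <- tidyr::expand_grid(frame = seq_len(n_f), k = seq_len(n_c))
    cand$camera <- "c"; cand$joint <- "j"
    cand$x <- runif(nrow(cand), 0, 200)
    cand$y <- runif(nrow(cand), 0, 200)
    cand$score <- runif(nrow(cand), 0.1, 1)
    sigma <- 60
    got <- filter_keypoints_viterbi(cand, sigma = sigma, max_gap = 0,
                                    dedup_radius = 1e-6)
    # brute force over all n_c^n_f paths with the same weights
    paths <- do.call(expand.grid, rep(list(seq_len(n_c)), n_f))
    best <- -Inf; best_xy <- NULL
    for (r in seq_len(nrow(paths))) {
      sel <- purrr::map_dfr(seq_len(n_f), function(f) {
        cand[cand$frame == f, ][as.integer(paths[r, f]), ]
      })
      lp <- sum(log(sel$score)) -
        sum((diff(sel$x)^2 + diff(sel$y)^2) / (2 * sigma^2))
      if (lp > best) { best <- lp; best_xy <- sel }
    }
    expect_equal(got$x, best_xy$x, tolerance = 1e-9)
    expect_equal(got$y, best_xy$y, tolerance = 1e-9)
  }
})

test_that("viterbi bridges detection gaps with carryover and marks them missing", {
  # candidate missing at frame 3 entirely
  cand <- tibble::tibble(camera = "c", frame = c(1, 2, 4, 5), joint = "j",
                         x = c(0, 1, 3, 4), y = 0, score = 0.9)
  out <- filter_keypoints_viterbi(cand, sigma = 5, max_gap = 3)
  expect_true(is.na(out$x[out$frame == 3]))
  expect_equal(out$x[out$frame %in% c(1, 2, 4, 5)], c(0, 1, 3, 4))
})

test_that("viterbi filtering lowers 2D RMSE on corrupted trajectories", {
  set.seed(35)
  t <- seq_len(300)
  truth_x <- 200 + 80 * sin(t / 20); truth_y <- 150 + 50 * cos(t / 15)
  x <- truth_x + rnorm(300, sd = 2); y <- truth_y + rnorm(300, sd = 2)
  tele <- runif(300) < 0.05
  x[tele] <- x[tele] + sample(c(-1, 1), sum(tele), TRUE) * 120
  cand <- dplyr::bind_rows(
    tibble::tibble(camera = "c", frame = t, joint = "j", x = x, y = y,
                   score = 0.9),
    # spurious low-score second candidates
    tibble::tibble(camera = "c", frame = t, joint = "j",
                   x = truth_x + runif(300, -200, 200),
                   y = truth_y + runif(300, -200, 200), score = 0.3)
  )
  out <- filter_keypoints_viterbi(cand, sigma = 10, max_gap = 5)
  rmse <- function(xh, yh, keep = !is.na(xh)) {
    sqrt(mean((xh[keep] - truth_x[keep])^2 + (yh[keep] - truth_y[keep])^2))
  }
  raw_rmse <- rmse(x, y, rep(TRUE, 300))
  vit_rmse <- rmse(out$x, out$y)
  expect_lt(vit_rmse, raw_rmse)
})
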