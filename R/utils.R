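#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd rnorm runif quantile fft qt setNames spline
#' @importFrom utils head tail
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed from a project seed
#'
#' All stochastic steps in the package draw their own seed from a single
#' project-level seed plus a stage label, so that adding or reordering
#' stages does not silently change unrelated random draws.
#'
#' @param seed Integer project seed.
#' @param tag Character label of the stage requesting randomness.
#' @return An integer seed in `[0, 2^31)`.
#' @export
sub_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) + 1000003 * (h %% 104729)) %% 2147483647)
}

#' Power spectral density by Welch's method
#'
#' Averaged modified periodograms over Hann-windowed, 50%-overlapping
#' segments. Matches the conventional one-sided density scaling.
#'
#' @param x Numeric vector (evenly sampled signal).
#' @param fs Sampling rate (Hz or cycles/sample when `fs = 1`).
#' @param nperseg Segment length; defaults to `min(256, length(x))`.
#' @return A tibble with columns `freq` and `power`.
#' @export
welch_psd <- function(x, fs = 1, nperseg = min(256L, length(x))) {
  x <- as.numeric(x)
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1)) # Hann
  scale <- fs * sum(w^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 / scale
    p <- sp[seq_len(nf)]
    # double interior bins for the one-sided density
    if (nperseg %% 2 == 0) {
      if (nf > 2) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    } else if (nf > 1) {
      p[2:nf] <- 2 * p[2:nf]
    }
    acc <- acc + p
  }
  tibble(freq = (seq_len(nf) - 1L) * fs / nperseg, power = acc / length(starts))
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' argument is the instantaneous phase.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Unwrap a phase or angle series
#'
#' @param x Numeric vector of angles.
#' @param period Period of the wrap (default `2*pi`; use 360 for degrees).
#' @return Unwrapped series.
#' @export
unwrap_angle <- function(x, period = 2 * pi) {
  ok <- !is.na(x)
  y <- x
  xs <- x[ok]
  if (length(xs) > 1) {
    d <- diff(xs)
    d <- d - period * round(d / period)
    y[ok] <- xs[1] + c(0, cumsum(d))
  }
  y
}

# interpolate NA runs of length <= max_gap; method "spline" or "linear"
interp_gaps <- function(x, max_gap = Inf, method = "spline") {
  if (all(is.na(x)) || !anyNA(x)) return(x)
  filled <- if (method == "spline" && sum(!is.na(x)) >= 4) {
    as.numeric(zoo::na.spline(zoo::zoo(x), na.rm = FALSE))
  } else {
    as.numeric(zoo::na.approx(zoo::zoo(x), na.rm = FALSE))
  }
  if (is.finite(max_gap)) {
    r <- rle(is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (r$values[i] && r$lengths[i] > max_gap) {
        filled[starts[i]:ends[i]] <- NA_real_
      }
    }
  }
  # never extrapolate beyond the first/last observation
  obs <- which(!is.na(x))
  if (length(obs)) {
    if (obs[1] > 1) filled[seq_len(obs[1] - 1L)] <- NA_real_
    if (obs[length(obs)] < length(x)) {
      filled[(obs[length(obs)] + 1L):length(x)] <- NA_real_
    }
  }
  filled
}

# rolling median that tolerates missing values (centered window)
rolling_median <- function(x, window) {
  stopifnot(window %% 2 == 1)
  if (window > length(x)) abort("median filter window larger than the series")
  half <- (window - 1L) / 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    v <- x[lo:hi]
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  }, numeric(1))
}
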