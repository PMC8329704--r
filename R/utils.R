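# Internal numerical helpers shared across modules.

#' Zero-phase Butterworth band-pass
#'
#' Filters a signal (or each row of a channel-by-sample matrix) with a
#' Butterworth band-pass applied forwards and backwards (zero phase).
#'
#' @param x numeric vector, or matrix with one channel per row.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; `high` must be below the Nyquist rate.
#' @param order filter order (applied twice by the forward-backward pass).
#' @return filtered data with the shape of `x`.
#' @export
butterBandpass <- function(x, fs, low, high, order = 4L) {
  stopifnot(is.numeric(fs), fs > 0, low > 0, high > low)
  if (high >= fs / 2)
    stop("upper band edge (", high, " Hz) must be below Nyquist (", fs / 2, " Hz)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, function(ch) signal::filtfilt(bf, ch)))
    dimnames(out) <- dimnames(x)
    out
  } else {
    signal::filtfilt(bf, x)
  }
}

# 1/f ("pink") noise via spectral shaping of white noise; unit-variance output.
pinkNoise <- function(n) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)          # symmetric frequency index, keeps x real
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Midrank ranks down the rows of a matrix (each column ranked independently).
colRanks <- function(m) apply(m, 2L, rank)

# Linear detrend of each column of a T x V matrix (removes intercept + slope).
detrendColumns <- function(y) {
  if (!is.matrix(y)) y <- matrix(y, ncol = 1L)
  tt <- seq_len(nrow(y))
  X <- cbind(1, tt)
  y - X %*% solve(crossprod(X), crossprod(X, y))
}

# Fisher z with clipping just inside +/-1.
fisherZ <- function(r, clip = 1 - 1e-7) {
  clipped <- abs(r) >= 1
  if (any(clipped, na.rm = TRUE)) {
    warning("correlations at |r| = 1 clipped to ", format(clip), " before atanh")
    r <- pmin(pmax(r, -clip), clip)
  }
  atanh(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed (keeps derived seeds within 32-bit integer range).
childSeed <- function(seed, k) as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
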