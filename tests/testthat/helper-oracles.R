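# Independent brute-force oracles. These deliberately avoid the package's
# code paths (explicit DFT loops, literal textbook formulas) so that
# agreement is evidence of correctness rather than self-consistency.

# Explicit DFT of one window; band power as the package defines it
# (one-sided periodogram summed over bins with centre frequency in the band).
oracleWindowBandPower <- function(x, fs, band) {
  n <- length(x)
  kmax <- n %/% 2
  p <- 0
  for (k in 0:kmax) {
    f <- k * fs / n
    if (f < band[1] || f > band[2]) next
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    p <- p + (2 / n^2) * (re^2 + im^2)
  }
  p
}

# Mean of Hamming-tapered modified periodograms, explicit DFT.
oracleWelch <- function(x, fs, nfft, overlap = 0.5) {
  step <- max(1, round(nfft * (1 - overlap)))
  starts <- seq(1, length(x) - nfft + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  nkeep <- nfft %/% 2 + 1
  acc <- numeric(nkeep)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * w
    for (k in 0:(nkeep - 1)) {
      re <- sum(seg * cos(-2 * pi * k * (0:(nfft - 1)) / nfft))
      im <- sum(seg * sin(-2 * pi * k * (0:(nfft - 1)) / nfft))
      p <- (re^2 + im^2) / (fs * sum(w^2))
      if (k > 0 && (k < nkeep - 1 || nfft %% 2 == 1)) p <- 2 * p
      acc[k + 1] <- acc[k + 1] + p
    }
  }
  list(freq = (0:(nkeep - 1)) * fs / nfft, psd = acc / length(starts))
}

# Explicit-DFT amplitude-spectrum mean / fraction, after the same linear
# detrend the package applies (refit here with lm for independence).
oracleDetrend <- function(x) stats::residuals(stats::lm(x ~ seq_along(x)))

oracleAlff <- function(x, tr, band = c(0.01, 0.08), detrend = TRUE) {
  if (detrend) x <- oracleDetrend(x) else x <- x - mean(x)
  n <- length(x)
  amps <- freqs <- numeric(0)
  for (k in 1:(n %/% 2)) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    amps <- c(amps, 2 * sqrt(re^2 + im^2) / n)
    freqs <- c(freqs, k / (n * tr))
  }
  sel <- freqs >= band[1] & freqs <= band[2]
  list(alff = mean(amps[sel]), falff = sum(amps[sel]) / sum(amps))
}

# Textbook Kendall's W with tie correction: W = 12 S / (m^2 (T^3 - T) - m
# sum(t^3 - t)), S the sum of squared deviations of rank sums.
oracleKendallW <- function(seriesList) {
  m <- length(seriesList)
  T <- length(seriesList[[1]])
  R <- colSums(do.call(rbind, lapply(seriesList, rank)))
  S <- sum((R - mean(R))^2)
  ties <- sum(vapply(seriesList, function(v) {
    tab <- table(v); sum(tab^3 - tab)
  }, numeric(1)))
  12 * S / (m^2 * (T^3 - T) - m * ties)
}

# Literal Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k alpha / m; reject those, and compute adjusted p by the
# running-minimum definition.
oracleBH <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- min(running, 1)
  }
  k <- which(sort(p) <= (1:m) * alpha / m)
  rejected <- logical(m)
  if (length(k)) rejected[o[1:max(k)]] <- TRUE
  list(q = q, rejected = rejected)
}

# A tiny all-modality cohort configuration used by several tests.
miniCohortConfig <- function(n = 10, seed = 7L, effects = list(), ...) {
  cohortConfig(
    nParticipants = n, nSessions = 2, runsPerSession = 4, runDurationS = 12,
    fsNfb = 250, fsEeg = 250, eegDurationS = 4, nChannels = 40,
    gridShape = c(8L, 8L, 8L), nVolumes = 40, nRois = 4, roiRadiusMm = 4,
    effects = effects, seed = seed, ...)
}

fastFeedbackConfig <- function(...) feedbackConfig(windowS = 2, ...)
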