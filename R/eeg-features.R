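# Resting-state EEG spectral features: Welch PSD, relative band power,
# scalp-ROI aggregation.

#' Frequency band scheme
#'
#' The four analysis bands (theta 4-8, alpha 8-12, SMR 12-15, beta 12.5-30 Hz;
#' SMR and beta overlap by construction) and the full-band denominator range
#' used for relative power (default 1-100 Hz, the preprocessing band).
#'
#' @param theta,alpha,smr,beta numeric(2) band edges in Hz.
#' @param fullBand numeric(2) denominator range in Hz.
#' @return named list of bands with attribute `fullBand`.
#' @export
bandScheme <- function(theta = c(4, 8), alpha = c(8, 12), smr = c(12, 15),
                       beta = c(12.5, 30), fullBand = c(1, 100)) {
  bands <- list(theta = theta, alpha = alpha, smr = smr, beta = beta)
  for (b in bands)
    if (b[1] < fullBand[1] || b[2] > fullBand[2])
      stop("every band must lie within fullBand")
  structure(bands, fullBand = fullBand)
}

#' Nine-region scalp ROI map
#'
#' Standard frontal/central/parietal x left/middle/right partition of the
#' 10-10 montage used for topographic band-power screening. Channel lists are
#' disjoint across ROIs.
#'
#' @return named list of character vectors of channel labels.
#' @export
scalpRoiMap <- function() {
  list(
    leftFrontal    = c("F5", "F3", "FC5", "FC3"),
    middleFrontal  = c("F1", "Fz", "F2", "FC1", "FCz", "FC2"),
    rightFrontal   = c("F4", "F6", "FC4", "FC6"),
    leftCentral    = c("C5", "C3", "CP5", "CP3"),
    middleCentral  = c("C1", "Cz", "C2", "CP1", "CPz", "CP2"),
    rightCentral   = c("C4", "C6", "CP4", "CP6"),
    leftParietal   = c("P5", "P3", "PO7", "PO3"),
    middleParietal = c("P1", "Pz", "P2", "POz"),
    rightParietal  = c("P4", "P6", "PO4", "PO8"))
}

#' Preprocess a resting recording into 1-s epochs
#'
#' Band-pass filters every channel (default 1-100 Hz), re-references to the
#' common average, and cuts the recording into non-overlapping 1-s epochs
#' (trailing partial second discarded).
#'
#' @param signal channels-by-samples numeric matrix with channel rownames.
#' @param fs sampling rate in Hz; must exceed 200 Hz and twice the upper band
#'   edge.
#' @param band numeric(2) filter band in Hz.
#' @param reref logical, apply common-average re-referencing.
#' @return list of channels-by-`fs` epoch matrices.
#' @export
preprocessResting <- function(signal, fs, band = c(1, 100), reref = TRUE) {
  stopifnot(is.matrix(signal), !is.null(rownames(signal)))
  if (fs <= 200) stop("fs must exceed 200 Hz")
  if (ncol(signal) < fs) stop("recording shorter than 1 s")
  x <- butterBandpass(signal, fs, band[1], band[2])
  if (reref) x <- sweep(x, 2L, colMeans(x))
  nEpochs <- floor(ncol(x) / fs)
  lapply(seq_len(nEpochs), function(e)
    x[, ((e - 1) * fs + 1):(e * fs), drop = FALSE])
}

#' Welch power spectral density
#'
#' Mean of modified periodograms: segments of `nfft` samples with fractional
#' `overlap` and a Hamming taper, one-sided density scaling (the PSD
#' integrates to the signal variance over [0, fs/2]).
#'
#' @param x numeric vector, or channels-by-samples matrix (PSD per row).
#' @param fs sampling rate, Hz.
#' @param nfft segment/FFT length in samples (default 1000).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd` (vector, or channels-by-freq
#'   matrix).
#' @export
welchPsd <- function(x, fs, nfft = 1000L, overlap = 0.5) {
  if (is.matrix(x)) {
    res <- apply(x, 1L, function(ch) welchPsd(ch, fs, nfft, overlap)$psd)
    return(list(freq = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft,
                psd = t(res)))
  }
  n <- length(x)
  if (n < nfft)
    stop("input of ", n, " samples shorter than the minimum segment length ",
         nfft)
  step <- max(1L, round(nfft * (1 - overlap)))
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1))  # Hamming
  u <- sum(w^2)
  nkeep <- nfft %/% 2 + 1L
  segs <- matrix(x[outer(seq_len(nfft) - 1L, starts, `+`)], nrow = nfft)
  X <- stats::mvfft(segs * w)[seq_len(nkeep), , drop = FALSE]
  P <- Mod(X)^2 / (fs * u)
  P[2:(nkeep - 1L), ] <- 2 * P[2:(nkeep - 1L), ]  # one-sided doubling
  if (nfft %% 2L == 1L) P[nkeep, ] <- 2 * P[nkeep, ]
  list(freq = (seq_len(nkeep) - 1) * fs / nfft, psd = rowMeans(P))
}

#' Relative band power from a PSD
#'
#' Power integrated over the band (bins whose centre frequency lies inside the
#' band, endpoints inclusive) divided by the power integrated over the full
#' band; a dimensionless fraction in [0, 1].
#'
#' @param psd list as returned by [welchPsd()] (vector `psd`).
#' @param band numeric(2) band edges, Hz; a zero-width band is an error.
#' @param fullBand numeric(2) denominator range, Hz.
#' @return scalar fraction.
#' @export
relativeBandPower <- function(psd, band, fullBand = c(1, 100)) {
  stopifnot(is.list(psd), !is.null(psd$freq))
  if (band[2] <= band[1]) stop("zero- or negative-width band")
  num <- psd$freq >= band[1] & psd$freq <= band[2]
  den <- psd$freq >= fullBand[1] & psd$freq <= fullBand[2]
  if (!any(den)) stop("fullBand contains no spectral bins")
  sum(psd$psd[num]) / sum(psd$psd[den])
}

#' Scalp-ROI band-power table
#'
#' Per band: the relative power of every epoch and channel is computed and
#' z-standardised across all epochs and channels of the recording jointly
#' (this removes the recording-level scale while preserving the scalp
#' topography; a per-channel standardisation would also erase the
#' between-participant level differences the screening stage looks for).
#' Per channel, the median across epochs is then taken, and the ROI value is
#' the mean over its channels. A band with zero dispersion returns 0 with a
#' warning.
#'
#' @param epochs list of channels-by-samples epoch matrices (from
#'   [preprocessResting()]).
#' @param fs sampling rate, Hz.
#' @param roiMap named list of channel vectors (default [scalpRoiMap()]).
#' @param bands a [bandScheme()].
#' @param nfft Welch segment length; defaults to the epoch length so a 1-s
#'   epoch at 1000 Hz gives the standard 1000-point FFT.
#' @return ROI-by-band numeric matrix.
#' @export
roiBandTable <- function(epochs, fs, roiMap = scalpRoiMap(),
                         bands = bandScheme(), nfft = NULL) {
  stopifnot(length(epochs) >= 1L)
  chans <- rownames(epochs[[1]])
  missing <- setdiff(unlist(roiMap), chans)
  if (length(missing))
    stop("ROI channels missing from the recording: ",
         paste(missing, collapse = ", "))
  if (is.null(nfft)) nfft <- ncol(epochs[[1]])
  fullBand <- attr(bands, "fullBand")
  used <- unique(unlist(roiMap))
  # epochs x channels x bands array of relative powers
  rel <- vapply(epochs, function(ep) {
    W <- welchPsd(ep[used, , drop = FALSE], fs, nfft = nfft)
    vapply(bands, function(b) {
      num <- W$freq >= b[1] & W$freq <= b[2]
      den <- W$freq >= fullBand[1] & W$freq <= fullBand[2]
      rowSums(W$psd[, num, drop = FALSE]) / rowSums(W$psd[, den, drop = FALSE])
    }, numeric(length(used)))
  }, matrix(0, length(used), length(bands)))
  # standardise each band jointly across epochs and channels, then take the
  # per-channel median across epochs
  chanVal <- matrix(0, length(used), length(bands),
                    dimnames = list(used, names(bands)))
  for (b in seq_along(bands)) {
    v <- matrix(rel[, b, ], nrow = length(used))   # channels x epochs
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("zero dispersion in band '", names(bands)[b],
              "'; returning 0", call. = FALSE)
      next
    }
    z <- (v - mean(v)) / s
    chanVal[, b] <- apply(z, 1L, stats::median)
  }
  out <- t(vapply(roiMap, function(ch)
    colMeans(chanVal[ch, , drop = FALSE]), numeric(length(bands))))
  dimnames(out) <- list(names(roiMap), names(bands))
  out
}
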