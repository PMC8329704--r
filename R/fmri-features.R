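# Resting-state fMRI regional metrics (ALFF, fALFF, ReHo), map normalisation
# and smoothing, ROI-sphere extraction and functional connectivity.

#' Band-pass filter fMRI time series
#'
#' Zero-phase Butterworth band-pass (default 0.01-0.1 Hz) with mean removal,
#' applied to a vector or to each column of a time-by-voxel matrix.
#'
#' @param series numeric vector or T-by-V matrix.
#' @param tr repetition time, seconds.
#' @param low,high band edges, Hz.
#' @param order Butterworth order.
#' @return filtered series, same shape.
#' @export
bandpassTimeseries <- function(series, tr, low = 0.01, high = 0.1,
                               order = 2L) {
  fs <- 1 / tr
  m <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  m <- sweep(m, 2L, colMeans(m))
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- apply(m, 2L, function(v) signal::filtfilt(bf, v))
  if (is.matrix(series)) out else drop(out)
}

# One-sided FFT amplitude spectrum (2|X_k|/T) of each column; returns
# list(freq, amp) with the zero bin dropped.
amplitudeSpectrum <- function(y, tr) {
  if (!is.matrix(y)) y <- matrix(y, ncol = 1L)
  T <- nrow(y)
  nkeep <- T %/% 2 + 1L
  A <- 2 * Mod(stats::mvfft(y)[seq_len(nkeep), , drop = FALSE]) / T
  list(freq = ((seq_len(nkeep) - 1) / (T * tr))[-1L],
       amp = A[-1L, , drop = FALSE])
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Mean of the one-sided FFT amplitude spectrum over the low-frequency band
#' (default 0.01-0.08 Hz), computed on the unfiltered series after linear
#' detrending. Scales linearly with signal amplitude.
#'
#' @param series numeric vector or T-by-V matrix (one voxel per column),
#'   not band-pass filtered.
#' @param tr repetition time, seconds.
#' @param band numeric(2) low-frequency band, Hz.
#' @param detrend remove a per-voxel linear trend first (default TRUE; drift
#'   otherwise dominates the low-frequency bins).
#' @return scalar (vector input) or per-voxel numeric vector.
#' @export
alff <- function(series, tr, band = c(0.01, 0.08), detrend = TRUE) {
  y <- as.matrix(series)
  y <- if (detrend) detrendColumns(y) else sweep(y, 2L, colMeans(y))
  sp <- amplitudeSpectrum(y, tr)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(sel)) stop("no frequency bin falls inside the ALFF band; ",
                      "series too short for TR = ", tr)
  out <- colMeans(sp$amp[sel, , drop = FALSE])
  if (is.matrix(series)) out else out[[1L]]
}

#' Fractional ALFF
#'
#' Sum of in-band amplitudes divided by the sum of amplitudes over the whole
#' detectable range (0, Nyquist]; a fraction in [0, 1], invariant to amplitude
#' rescaling.
#'
#' @inheritParams alff
#' @export
falff <- function(series, tr, band = c(0.01, 0.08), detrend = TRUE) {
  y <- as.matrix(series)
  y <- if (detrend) detrendColumns(y) else sweep(y, 2L, colMeans(y))
  sp <- amplitudeSpectrum(y, tr)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  out <- colSums(sp$amp[sel, , drop = FALSE]) / colSums(sp$amp)
  if (is.matrix(series)) out else out[[1L]]
}

#' Regional homogeneity (Kendall's coefficient of concordance)
#'
#' For every in-mask voxel, Kendall's W over the time-point ranks of the voxel
#' and its 26 nearest neighbours (3x3x3 neighbourhood), with the standard tie
#' correction. Computed on band-passed, unsmoothed data. Voxels whose in-mask
#' neighbourhood (incl. themselves) has fewer than `minNeighbors` members get
#' 0.
#'
#' @param vol4d 4D array (x, y, z, t), band-passed and unsmoothed.
#' @param mask logical 3D array.
#' @param minNeighbors minimum neighbourhood size (default 9).
#' @return 3D array of W values in [0, 1] (0 outside the mask).
#' @export
reho <- function(vol4d, mask, minNeighbors = 9L) {
  d <- dim(vol4d)
  if (d[4] < 2L) stop("need at least 2 time points")
  stopifnot(all(dim(mask) == d[1:3]))
  T <- d[4]
  flat <- matrix(vol4d, nrow = prod(d[1:3]), ncol = T)
  ranks <- matrix(0, nrow(flat), T)
  idxMask <- which(mask)
  ranks[idxMask, ] <- t(apply(flat[idxMask, , drop = FALSE], 1L, rank))
  # per-voxel tie correction term sum(t^3 - t) over tie groups
  tieTerm <- numeric(nrow(flat))
  tieTerm[idxMask] <- apply(flat[idxMask, , drop = FALSE], 1L, function(v) {
    tab <- table(v); sum(tab^3 - tab)
  })
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- array(0, d[1:3])
  coords <- arrayInd(idxMask, d[1:3])
  for (i in seq_along(idxMask)) {
    nb <- sweep(off, 2L, coords[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    lin <- lin[mask[lin]]
    m <- length(lin)
    if (m < minNeighbors) next
    R <- colSums(ranks[lin, , drop = FALSE])
    S <- sum((R - mean(R))^2)
    denom <- m^2 * (T^3 - T) / 12 - m * sum(tieTerm[lin]) / 12
    if (denom > 0) out[idxMask[i]] <- S / denom
  }
  out
}

#' Z-standardise a map within a mask
#'
#' Subtracts the within-mask mean and divides by the within-mask standard
#' deviation; voxels outside the mask are set to 0.
#'
#' @param map 3D numeric array.
#' @param mask logical 3D array.
#' @return standardised 3D array.
#' @export
zStandardizeMap <- function(map, mask) {
  v <- map[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("constant map within mask: zero SD")
  out <- array(0, dim(map))
  out[mask] <- (v - mean(v)) / s
  out
}

#' Gaussian smoothing of a 3D map
#'
#' Separable Gaussian kernel with sigma = FWHM / (2 sqrt(2 ln 2)) per axis
#' (in voxel units), symmetric (half-sample reflective) boundary handling.
#'
#' @param map 3D numeric array, or a 4D array (each time point smoothed
#'   along the three spatial axes).
#' @param fwhmMm full width at half maximum, mm.
#' @param voxelSizeMm isotropic voxel size, mm.
#' @return smoothed array, same shape.
#' @export
gaussianSmooth <- function(map, fwhmMm, voxelSizeMm = 3) {
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSizeMm
  if (sigma <= 0) return(map)
  rad <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  # per-axis smoothing matrix with half-sample symmetric reflection; rows sum
  # to 1 and (by symmetry) columns too, so the map total is preserved
  smat <- function(n) {
    S <- matrix(0, n, n)
    for (i in seq_len(n)) for (o in -rad:rad) {
      j <- i + o
      while (j < 1L || j > n) j <- if (j < 1L) 1L - j else 2L * n + 1L - j
      S[i, j] <- S[i, j] + k[o + rad + 1L]
    }
    S
  }
  d <- dim(map)
  nax <- length(d)
  out <- map
  for (ax in 1:3) {
    p <- c(ax, setdiff(seq_len(nax), ax))
    b <- aperm(out, p)
    db <- dim(b)
    b <- array(smat(db[1]) %*% matrix(b, nrow = db[1]), db)
    out <- aperm(b, order(p))
  }
  out
}

#' Extract ROI-sphere mean time series
#'
#' Each ROI is a sphere of `radius` mm around a world-space centre; a voxel
#' belongs to the sphere when its centre (voxel index mapped through the
#' affine) lies within the radius, ties at exactly the radius included. The
#' ROI series is the mean over the sphere's in-mask voxels at every time
#' point.
#'
#' @param vol4d 4D array (x, y, z, t).
#' @param roiTable data.frame with columns name, x, y, z (mm) and optionally
#'   radius (mm, default 8).
#' @param mask logical 3D array (default: all voxels).
#' @param voxelSizeMm isotropic voxel size; voxel (i, j, k) maps to world
#'   ((i-1), (j-1), (k-1)) * voxelSizeMm.
#' @return ROI-by-time numeric matrix with ROI names as rownames.
#' @export
extractRoiSeries <- function(vol4d, roiTable, mask = NULL, voxelSizeMm = 3) {
  d <- dim(vol4d)
  if (length(d) != 4L) stop("expected a 4D volume")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  grid <- arrayInd(seq_len(prod(d[1:3])), d[1:3])
  world <- (grid - 1) * voxelSizeMm
  flat <- matrix(vol4d, nrow = prod(d[1:3]), ncol = d[4])
  radius <- if ("radius" %in% names(roiTable)) roiTable$radius else
    rep(8, nrow(roiTable))
  out <- matrix(NA_real_, nrow(roiTable), d[4],
                dimnames = list(roiTable$name, NULL))
  for (r in seq_len(nrow(roiTable))) {
    ctr <- as.numeric(roiTable[r, c("x", "y", "z")])
    d2 <- (world[, 1] - ctr[1])^2 + (world[, 2] - ctr[2])^2 +
          (world[, 3] - ctr[3])^2
    sel <- d2 <= radius[r]^2 & as.vector(mask)
    if (!any(sel))
      stop("ROI '", roiTable$name[r], "' contains no in-mask voxel")
    out[r, ] <- colMeans(flat[sel, , drop = FALSE])
  }
  out
}

#' Fisher-z functional connectivity matrix
#'
#' Pearson correlations between all ROI pairs, Fisher z-transformed
#' (atanh), with |r| = 1 clipped just inside the domain. The diagonal is
#' stored as 0 and excluded from analysis.
#'
#' @param roiSeries ROI-by-time matrix.
#' @return symmetric ROI-by-ROI matrix of z values, diagonal 0.
#' @export
fcMatrix <- function(roiSeries) {
  sds <- apply(roiSeries, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI series: ",
         paste(rownames(roiSeries)[sds == 0], collapse = ", "))
  r <- stats::cor(t(roiSeries))
  diag(r) <- 0
  z <- fisherZ(r)
  diag(z) <- 0
  z
}

#' Upper-triangle edge vector of a connectome
#'
#' @param z symmetric ROI-by-ROI matrix.
#' @return named numeric vector of upper-triangle edges (`roiA|roiB`).
#' @export
edgeVector <- function(z) {
  ut <- upper.tri(z)
  nm <- outer(rownames(z), colnames(z), paste, sep = "|")
  stats::setNames(z[ut], nm[ut])
}
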