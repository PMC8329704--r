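# Synthetic multimodal cohort generator with planted, parameterised
# feature-learning relations. Every downstream stage of the package is
# testable against cohorts from this module; ground truth is stored alongside
# the data but never consumed by any analysis function.

#' Standard 64-channel montage
#'
#' 10-10 labels covering all channels of the nine scalp ROIs
#' ([scalpRoiMap()]) plus standard peripheral sites.
#'
#' @param n number of channels to return (>= 40 so all ROI channels are
#'   present).
#' @return character vector of channel labels.
#' @export
montage64 <- function(n = 64L) {
  roi <- unique(unlist(scalpRoiMap()))
  extra <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
             "F7", "F8", "FT7", "FT8", "T7", "T8", "TP7", "TP8",
             "P7", "P8", "PO9", "PO10", "O1", "Oz", "O2", "Iz")
  labels <- c(roi, extra)
  if (n < length(roi))
    stop("montage must include the ", length(roi), " scalp-ROI channels")
  labels[seq_len(min(n, length(labels)))]
}

# Pearson correlation of a bivariate Gaussian whose Spearman correlation is
# rhoS (Gaussian copula identity rhoS = (6/pi) asin(rhoP/2)).
spearmanToPearson <- function(rhoS) 2 * sin(pi * rhoS / 6)

#' One synthetic NFB training run
#'
#' Broadband 1/f noise plus a narrowband SMR component (13.5 Hz sinusoid,
#' random phase) whose band power equals `power`, so the
#' run-median online SMR power recovers `power` plus a constant noise floor.
#'
#' @param power target SMR band power (a pure sinusoid of amplitude
#'   `sqrt(2 * power)`).
#' @param fs sampling rate, Hz.
#' @param durationS run duration, seconds (>= 10).
#' @param noiseSd standard deviation of the pink-noise background (0 for a
#'   noiseless run).
#' @param freq sinusoid frequency, Hz.
#' @return numeric vector of `durationS * fs` samples.
#' @export
synthNfbRun <- function(power, fs = 250, durationS = 180, noiseSd = 0.3,
                        freq = 13.5) {
  if (durationS < 10) stop("durationS must be at least 10 s")
  stopifnot(power >= 0)
  n <- round(durationS * fs)
  t <- seq_len(n) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  sig <- sqrt(2 * power) * sin(2 * pi * freq * t + phase)
  if (noiseSd > 0) sig <- sig + noiseSd * pinkNoise(n)
  sig
}

#' One synthetic resting EEG recording
#'
#' Each channel is unit-variance pink noise plus sinusoidal band oscillators
#' (theta 6 Hz, alpha 10 Hz, SMR 13.5 Hz, beta 20 Hz) with per-epoch random
#' phase. On `smrChannels` the SMR amplitude is scaled by
#' `exp(smrGain * smrLatent)`, a positive monotone map of the participant's
#' latent feature value.
#'
#' @param fs sampling rate, Hz.
#' @param durationS duration, seconds.
#' @param nChannels number of channels (labels from [montage64()]).
#' @param smrLatent participant latent value carried by the SMR amplitude.
#' @param smrChannels channels carrying the latent (e.g. the left-central
#'   ROI).
#' @param smrGain log-amplitude gain per latent unit.
#' @param oscAmps named amplitudes of the four oscillators.
#' @param noiseAmp pink-noise amplitude.
#' @param channelNames optional explicit channel labels.
#' @return channels-by-samples matrix with channel rownames.
#' @export
synthRestingEeg <- function(fs = 1000, durationS = 180, nChannels = 64L,
                            smrLatent = 0, smrChannels = character(),
                            smrGain = 0.3,
                            oscAmps = c(theta = 1, alpha = 1.5, smr = 1,
                                        beta = 0.8),
                            noiseAmp = 1, channelNames = NULL) {
  if (is.null(channelNames)) channelNames <- montage64(nChannels)
  missing <- setdiff(smrChannels, channelNames)
  if (length(missing))
    stop("smrChannels not in the montage: ", paste(missing, collapse = ", "))
  n <- round(durationS * fs)
  freqs <- c(theta = 6, alpha = 10, smr = 13.5, beta = 20)
  epoch <- fs                       # 1-s epochs, matching the analysis
  nEp <- ceiling(n / epoch)
  t <- seq_len(n) / fs
  epochOf <- rep(seq_len(nEp), each = epoch)[seq_len(n)]
  out <- matrix(0, length(channelNames), n,
                dimnames = list(channelNames, NULL))
  for (ch in seq_along(channelNames)) {
    x <- noiseAmp * pinkNoise(n)
    for (b in names(freqs)) {
      amp <- oscAmps[[b]]
      if (b == "smr" && channelNames[ch] %in% smrChannels)
        amp <- amp * exp(smrGain * smrLatent)
      phases <- stats::runif(nEp, 0, 2 * pi)
      x <- x + amp * sin(2 * pi * freqs[[b]] * t + phases[epochOf])
    }
    out[ch, ] <- x
  }
  out
}

# Linear indices of a voxel sphere (centre in voxel indices, radius in
# voxels); errors if the sphere leaves the grid or misses the mask.
sphereVoxels <- function(center, radius, gridShape, mask = NULL,
                         what = "cluster") {
  if (any(center < 1) || any(center > gridShape))
    stop(what, " centre ", paste(center, collapse = ","),
         " outside the grid")
  grid <- arrayInd(seq_len(prod(gridShape)), gridShape)
  d2 <- rowSums(sweep(grid, 2L, center)^2)
  sel <- which(d2 <= radius^2)
  if (!is.null(mask)) sel <- sel[mask[sel]]
  if (!length(sel)) stop(what, " contains no in-mask voxel")
  sel
}

#' One synthetic rsfMRI 4D volume
#'
#' Gaussian background noise inside the mask, with three kinds of planted
#' structure: ALFF clusters receive an added low-frequency sinusoid whose
#' amplitude is a positive monotone map of the participant latent; ReHo
#' clusters share a common time course (rank-correlating neighbours); FC
#' edge spheres share a common band-limited signal whose weight is a
#' monotone map of the latent.
#'
#' @param gridShape voxel dimensions.
#' @param nVolumes number of time points.
#' @param tr repetition time, seconds.
#' @param mask logical 3D array (default all voxels).
#' @param alffClusters list of `list(voxels=, latent=)` entries.
#' @param rehoClusters list of `list(voxels=, weight=)` entries.
#' @param fcEdges list of `list(voxelsA=, voxelsB=, latent=)` entries.
#' @param noiseSd background noise SD.
#' @param alffGain,fcGain log-scale gains applied to the latents.
#' @param alffFreq frequency of the planted ALFF oscillation, Hz.
#' @return 4D array (x, y, z, t).
#' @export
synthFmri <- function(gridShape = c(16L, 16L, 16L), nVolumes = 100L, tr = 2,
                      mask = NULL, alffClusters = list(),
                      rehoClusters = list(), fcEdges = list(),
                      noiseSd = 1, alffGain = 0.4, fcGain = 0.6,
                      alffFreq = 0.03) {
  if (is.null(mask)) mask <- array(TRUE, gridShape)
  nvox <- prod(gridShape)
  flat <- matrix(0, nvox, nVolumes)
  flat[mask, ] <- stats::rnorm(sum(mask) * nVolumes, sd = noiseSd)
  tt <- seq_len(nVolumes) * tr
  for (cl in c(alffClusters, rehoClusters, fcEdges))
    if (!length(cl$voxels %||% c(cl$voxelsA, cl$voxelsB)))
      stop("planted cluster resolves to no voxels")
  for (cl in alffClusters) {
    amp <- 2 * exp(alffGain * cl$latent)
    flat[cl$voxels, ] <- flat[cl$voxels, , drop = FALSE] +
      rep(amp * sin(2 * pi * alffFreq * tt + stats::runif(1, 0, 2 * pi)),
          each = length(cl$voxels))
  }
  for (cl in rehoClusters) {
    shared <- bandpassTimeseries(stats::rnorm(nVolumes), tr)
    shared <- shared / stats::sd(shared)
    flat[cl$voxels, ] <- flat[cl$voxels, , drop = FALSE] +
      rep(cl$weight * shared, each = length(cl$voxels))
  }
  for (ed in fcEdges) {
    shared <- bandpassTimeseries(stats::rnorm(nVolumes), tr)
    shared <- shared / stats::sd(shared)
    w <- exp(fcGain * ed$latent)
    vox <- c(ed$voxelsA, ed$voxelsB)
    flat[vox, ] <- flat[vox, , drop = FALSE] +
      rep(w * shared, each = length(vox))
  }
  array(flat, c(gridShape, nVolumes))
}

#' One pair of synthetic morphometry maps
#'
#' Smooth random fields (Gaussian-smoothed white noise); inside each planted
#' cluster the intensity is shifted by `gain * latent`, the latent carrying
#' the configured rank correlation with the true learning slope.
#'
#' @param gridShape voxel dimensions.
#' @param clusters named list per tissue (`gmv`, `wmv`) of
#'   `list(voxels=, latent=, gain=)` entries.
#' @param noiseSd field noise SD before smoothing.
#' @param smoothFwhmMm,voxelSizeMm field smoothness.
#' @return list with `gmv` and `wmv` 3D arrays.
#' @export
synthMorphometry <- function(gridShape = c(16L, 16L, 16L),
                             clusters = list(gmv = list(), wmv = list()),
                             noiseSd = 1, smoothFwhmMm = 6, voxelSizeMm = 3) {
  oneMap <- function(cls) {
    m <- gaussianSmooth(array(stats::rnorm(prod(gridShape), sd = noiseSd),
                              gridShape), smoothFwhmMm, voxelSizeMm)
    for (cl in cls) m[cl$voxels] <- m[cl$voxels] + cl$gain * cl$latent
    m
  }
  list(gmv = oneMap(clusters$gmv), wmv = oneMap(clusters$wmv))
}

# Deterministic ROI sphere table inside the synthetic grid.
synthRoiTable <- function(config) {
  networks <- c("cerebellar", "cingulo-opercular", "default mode",
                "frontoparietal", "occipital", "sensorimotor", "emotional")
  extentMm <- config@gridShape * config@voxelSizeMm
  spacing <- max(2 * config@roiRadiusMm * 0.75, config@voxelSizeMm)
  ax <- lapply(extentMm, function(e) {
    s <- seq(config@roiRadiusMm, e - config@roiRadiusMm, by = spacing)
    if (!length(s)) e / 2 else s
  })
  cand <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  if (nrow(cand) < config@nRois)
    stop("grid too small for ", config@nRois, " ROI spheres")
  pick <- cand[sample.int(nrow(cand), config@nRois), , drop = FALSE]
  data.frame(name = sprintf("roi%03d", seq_len(config@nRois)),
             x = pick[, 1], y = pick[, 2], z = pick[, 3],
             radius = config@roiRadiusMm,
             network = rep(networks, length.out = config@nRois))
}

# Resolve a PlantedEffect's target to concrete geometry; configuration errors
# name the offending effect.
resolveEffectTarget <- function(effect, config, mask, roiTable) {
  tag <- paste0(effect@modality, " effect")
  tg <- effect@target
  if (effect@modality == "eeg_power") {
    roiMap <- scalpRoiMap()
    if (is.null(tg$roi) || !tg$roi %in% names(roiMap))
      stop("configuration error in ", tag, ": unknown scalp ROI '",
           tg$roi, "'")
    list(channels = roiMap[[tg$roi]],
         condition = if (is.null(tg$condition)) "eo" else tg$condition)
  } else if (effect@modality == "fc") {
    if (is.null(tg$edge) || length(tg$edge) != 2L ||
        any(tg$edge < 1) || any(tg$edge > nrow(roiTable)))
      stop("configuration error in ", tag, ": edge must index two ROIs")
    vs <- config@voxelSizeMm
    vox <- lapply(tg$edge, function(i) {
      ctr <- round(as.numeric(roiTable[i, c("x", "y", "z")]) / vs) + 1L
      sphereVoxels(ctr, config@roiRadiusMm / vs, config@gridShape, mask, tag)
    })
    list(voxelsA = vox[[1]], voxelsB = vox[[2]], edge = tg$edge)
  } else {
    if (is.null(tg$center))
      stop("configuration error in ", tag, ": target needs a centre")
    radius <- if (is.null(tg$radius)) 2 else tg$radius
    list(voxels = sphereVoxels(tg$center, radius, config@gridShape, mask,
                               tag))
  }
}

#' Generate a synthetic multimodal cohort
#'
#' Draws the true learning slope and all planted latent feature values from
#' a joint Gaussian (Gaussian copula), so each planted effect's noise-free
#' latent has exactly the configured Spearman correlation with the slope in
#' the population. Then synthesises, per participant, the requested
#' modalities: NFB training runs, resting EEG (eyes-open and eyes-closed),
#' an fMRI 4D volume, and gray/white-matter maps. The output is fully
#' determined by `config@seed`.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param modalities character subset of `c("nfb", "eeg", "fmri", "smri")`
#'   to synthesise (all by default; skipping unneeded modalities keeps small
#'   test cohorts fast).
#' @return a \linkS4class{CohortDataset} (with ground truth attached).
#' @export
generateCohort <- function(config,
                           modalities = c("nfb", "eeg", "fmri", "smri")) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  modalities <- if (length(modalities))
    match.arg(modalities, c("nfb", "eeg", "fmri", "smri"), several.ok = TRUE)
  else character()
  set.seed(config@seed)
  n <- config@nParticipants
  mask <- array(TRUE, config@gridShape)
  roiTable <- synthRoiTable(config)
  effects <- config@effects
  geom <- lapply(effects, resolveEffectTarget, config = config, mask = mask,
                 roiTable = roiTable)

  # --- latent layer (Gaussian copula) ----------------------------------
  zSlope <- stats::rnorm(n)
  trueSlope <- config@slopeMean + config@slopeSd * zSlope
  nE <- length(effects)
  latent <- matrix(0, n, nE)
  latentObs <- matrix(0, n, nE)
  for (e in seq_len(nE)) {
    rhoP <- spearmanToPearson(effects[[e]]@trueCorrelation)
    latent[, e] <- rhoP * zSlope + sqrt(1 - rhoP^2) * stats::rnorm(n)
    latentObs[, e] <- latent[, e] + effects[[e]]@noiseSd * stats::rnorm(n)
  }

  covariates <- data.frame(
    id = sprintf("sub%03d", seq_len(n)),
    age = round(stats::rnorm(n, 23.1, 2.36), 1),
    sex = factor(ifelse(stats::rbinom(n, 1, 12 / 27) == 1, "M", "F"),
                 levels = c("F", "M")))

  byMod <- function(mod) which(vapply(effects, function(e)
    e@modality == mod, logical(1)))

  nfb <- list(); eeg <- list(); fmri <- list(); gmv <- list(); wmv <- list()
  for (p in seq_len(n)) {
    if ("nfb" %in% modalities) {
      nfb[[p]] <- lapply(seq_len(config@nSessions), function(s)
        lapply(seq_len(config@runsPerSession) - 1L, function(r)
          synthNfbRun(max(config@basePower + trueSlope[p] * r,
                          config@powerFloor),
                      fs = config@fsNfb, durationS = config@runDurationS,
                      noiseSd = config@nfbNoiseSd)))
    }
    if ("eeg" %in% modalities) {
      eIdx <- byMod("eeg_power")
      mkRec <- function(cond) {
        lat <- 0; chans <- character()
        for (e in eIdx) if (geom[[e]]$condition == cond) {
          lat <- latentObs[p, e]; chans <- geom[[e]]$channels
        }
        synthRestingEeg(fs = config@fsEeg, durationS = config@eegDurationS,
                        nChannels = config@nChannels, smrLatent = lat,
                        smrChannels = chans)
      }
      eeg[[p]] <- list(eo = mkRec("eo"), ec = mkRec("ec"))
    }
    if ("fmri" %in% modalities) {
      fmri[[p]] <- synthFmri(
        gridShape = config@gridShape, nVolumes = config@nVolumes,
        tr = config@trS, mask = mask,
        alffClusters = lapply(byMod("alff"), function(e)
          list(voxels = geom[[e]]$voxels, latent = latentObs[p, e])),
        rehoClusters = lapply(byMod("reho"), function(e)
          list(voxels = geom[[e]]$voxels,
               weight = exp(0.5 * latentObs[p, e]))),
        fcEdges = lapply(byMod("fc"), function(e)
          list(voxelsA = geom[[e]]$voxelsA, voxelsB = geom[[e]]$voxelsB,
               latent = latentObs[p, e])))
    }
    if ("smri" %in% modalities) {
      mk <- function(mod) lapply(byMod(mod), function(e)
        list(voxels = geom[[e]]$voxels, latent = latentObs[p, e],
             gain = 1.5 * sign(effects[[e]]@trueCorrelation)))
      maps <- synthMorphometry(config@gridShape,
                               clusters = list(gmv = mk("gmv"),
                                               wmv = mk("wmv")),
                               voxelSizeMm = config@voxelSizeMm)
      gmv[[p]] <- maps$gmv; wmv[[p]] <- maps$wmv
    }
  }

  new("CohortDataset", nfb = nfb, eeg = eeg, fmri = fmri, gmv = gmv,
      wmv = wmv, mask = mask, roiTable = roiTable, covariates = covariates,
      config = config,
      groundTruth = list(trueSlope = trueSlope, latent = latent,
                         latentObserved = latentObs,
                         effectGeometry = geom))
}

#' Feature-level synthetic cohorts for prediction benchmarking
#'
#' Draws the four modality feature blocks directly from the latent layer:
#' the true learning index is the sum of four independent unit-variance
#' modality components (plus observation noise), and each modality's
#' features are noisy copies of its own component. This is the fast
#' generator used to exercise the multimodal-vs-single-modality prediction
#' property over many cohorts; the full imaging chain produces the same
#' structure one cohort at a time.
#'
#' @param n participants.
#' @param featuresPerModality columns per modality block.
#' @param featureNoiseSd noise SD on each feature copy.
#' @param liNoiseSd observation noise on the learning index.
#' @param seed integer seed.
#' @return list: `features` (named list of matrices: eeg, smri, alff, fc),
#'   `li` (numeric).
#' @export
synthFeatureCohort <- function(n = 27L, featuresPerModality = 3L,
                               featureNoiseSd = 1, liNoiseSd = 0.3,
                               seed = 1L) {
  set.seed(seed)
  mods <- c("eeg", "smri", "alff", "fc")
  z <- matrix(stats::rnorm(n * 4L), n, 4L, dimnames = list(NULL, mods))
  li <- rowSums(z) / 2 + liNoiseSd * stats::rnorm(n)
  features <- lapply(mods, function(m) {
    f <- matrix(z[, m], n, featuresPerModality) +
      featureNoiseSd * matrix(stats::rnorm(n * featuresPerModality), n)
    colnames(f) <- paste0(m, seq_len(featuresPerModality))
    f
  })
  names(features) <- mods
  list(features = features, li = li)
}
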