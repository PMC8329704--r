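#' @import methods
NULL

# ---------------------------------------------------------------------------
# FeedbackConfig
# ---------------------------------------------------------------------------

#' Online feedback engine configuration
#'
#' Parameters of the real-time SMR feedback computation: the feedback channel
#' is sampled at `fs` Hz, band-pass filtered to `onlineBand`, and band power in
#' `smrBand` is computed by an FFT over a sliding window of `windowS` seconds
#' advanced every `stepS` seconds. A reward point is granted for every maximal
#' above-threshold stretch lasting longer than `rewardHoldS` seconds.
#'
#' @slot fs sampling rate, Hz.
#' @slot onlineBand numeric(2), online band-pass edges in Hz.
#' @slot smrBand numeric(2), feedback (SMR) band in Hz.
#' @slot windowS analysis window length, seconds.
#' @slot stepS window step, seconds.
#' @slot rewardHoldS minimum above-threshold hold for a reward point, seconds.
#' @slot prefilter logical; apply the online band-pass before the FFT. Disable
#'   for already-clean signals (the zero-phase filter has non-unit pass-band
#'   gain of order 1e-4, which matters only to exact-recovery checks).
#' @slot taper `"rect"` (default) or `"hann"` window taper for the FFT.
#' @export
setClass("FeedbackConfig", representation(
  fs = "numeric", onlineBand = "numeric", smrBand = "numeric",
  windowS = "numeric", stepS = "numeric", rewardHoldS = "numeric",
  prefilter = "logical", taper = "character"
))

setValidity("FeedbackConfig", function(object) {
  msg <- character()
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (!(object@windowS > object@stepS && object@stepS > 0))
    msg <- c(msg, "need windowS > stepS > 0")
  if (length(object@smrBand) != 2L || length(object@onlineBand) != 2L)
    msg <- c(msg, "bands must be length-2 (low, high)")
  else if (object@smrBand[1] < object@onlineBand[1] ||
           object@smrBand[2] > object@onlineBand[2])
    msg <- c(msg, "smrBand must lie within onlineBand")
  if (!object@taper %in% c("rect", "hann")) msg <- c(msg, "unknown taper")
  if (length(msg)) msg else TRUE
})

#' Construct a feedback engine configuration
#'
#' Defaults follow the standard SMR up-regulation protocol: 250 Hz sampling,
#' 0.5-45 Hz online band, 12-15 Hz feedback band, a 10-s FFT window stepped
#' every 100 ms, and a 1-s reward hold.
#'
#' @param fs,onlineBand,smrBand,windowS,stepS,rewardHoldS,prefilter,taper see
#'   \linkS4class{FeedbackConfig}.
#' @return a \linkS4class{FeedbackConfig}.
#' @examples
#' feedbackConfig(windowS = 2)
#' @export
feedbackConfig <- function(fs = 250, onlineBand = c(0.5, 45),
                           smrBand = c(12, 15), windowS = 10, stepS = 0.1,
                           rewardHoldS = 1.0, prefilter = TRUE,
                           taper = "rect") {
  new("FeedbackConfig", fs = fs, onlineBand = onlineBand, smrBand = smrBand,
      windowS = windowS, stepS = stepS, rewardHoldS = rewardHoldS,
      prefilter = prefilter, taper = taper)
}

#' @export
setMethod("show", "FeedbackConfig", function(object) {
  cat("FeedbackConfig: fs=", object@fs, " Hz, band ", object@smrBand[1], "-",
      object@smrBand[2], " Hz, window ", object@windowS, " s / step ",
      object@stepS, " s\n", sep = "")
})

# ---------------------------------------------------------------------------
# PlantedEffect / CohortConfig
# ---------------------------------------------------------------------------

#' A planted feature-learning relation for the synthetic cohort generator
#'
#' Describes one baseline feature (an EEG scalp-ROI band power, a morphometry
#' or ALFF/ReHo voxel cluster, or a functional-connectivity edge) whose
#' across-participant values are generated to have a chosen Spearman rank
#' correlation with the true learning slope.
#'
#' @slot modality one of `"eeg_power"`, `"gmv"`, `"wmv"`, `"alff"`, `"reho"`,
#'   `"fc"`.
#' @slot target modality-specific location: for `eeg_power` a list with `roi`
#'   (scalp ROI name) and optional `condition`; for map modalities a list with
#'   `center` (voxel index triple) and `radius` (voxels); for `fc` a list with
#'   `edge` (two ROI indices).
#' @slot trueCorrelation target Spearman correlation with the true slope,
#'   strictly inside (-1, 1).
#' @slot noiseSd feature-level noise standard deviation added on top of the
#'   correlated latent (latent is unit variance).
#' @export
setClass("PlantedEffect", representation(
  modality = "character", target = "list",
  trueCorrelation = "numeric", noiseSd = "numeric"
))

setValidity("PlantedEffect", function(object) {
  msg <- character()
  if (!object@modality %in% c("eeg_power", "gmv", "wmv", "alff", "reho", "fc"))
    msg <- c(msg, paste0("unknown modality '", object@modality, "'"))
  if (abs(object@trueCorrelation) >= 1)
    msg <- c(msg, "|trueCorrelation| must be < 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PlantedEffect-class
#' @param modality,target,trueCorrelation,noiseSd see slots.
#' @export
plantedEffect <- function(modality, target, trueCorrelation, noiseSd = 0.5) {
  new("PlantedEffect", modality = modality, target = target,
      trueCorrelation = trueCorrelation, noiseSd = noiseSd)
}

#' Synthetic cohort configuration
#'
#' Holds the geometry, acquisition parameters and planted effects of a
#' synthetic multimodal neurofeedback cohort. Defaults mirror the study
#' conditions the package emulates: 27 participants, three training sessions
#' of 12 runs (index 0 the no-trend baseline run) of 180 s at 250 Hz; 64
#' channels of resting EEG at 1000 Hz; small abstract fMRI/morphometry grids
#' with a 3-mm isotropic voxel and identity-orientation affine.
#'
#' @slot nParticipants,nSessions,runsPerSession,runDurationS,fsNfb NFB block.
#' @slot fsEeg,eegDurationS,nChannels resting-EEG block.
#' @slot gridShape,nVolumes,trS,voxelSizeMm,nRois,roiRadiusMm imaging block.
#' @slot effects list of \linkS4class{PlantedEffect}.
#' @slot slopeMean,slopeSd distribution of the true learning slope (median
#'   SMR-power units per run).
#' @slot basePower,powerFloor,nfbNoiseSd NFB signal model parameters.
#' @slot seed integer RNG seed; fully determines the cohort.
#' @export
setClass("CohortConfig", representation(
  nParticipants = "integer", nSessions = "integer", runsPerSession = "integer",
  runDurationS = "numeric", fsNfb = "numeric",
  fsEeg = "numeric", eegDurationS = "numeric", nChannels = "integer",
  gridShape = "integer", nVolumes = "integer", trS = "numeric",
  voxelSizeMm = "numeric", nRois = "integer", roiRadiusMm = "numeric",
  effects = "list",
  slopeMean = "numeric", slopeSd = "numeric",
  basePower = "numeric", powerFloor = "numeric", nfbNoiseSd = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  counts <- c(object@nParticipants, object@nSessions, object@runsPerSession,
              object@nChannels, object@nVolumes, object@nRois)
  if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be three positive dimensions")
  if (object@trS <= 0) msg <- c(msg, "trS must be positive")
  if (object@runDurationS < 10)
    msg <- c(msg, "runDurationS must cover at least one 10-s feedback window")
  for (e in object@effects)
    if (!is(e, "PlantedEffect")) msg <- c(msg, "effects must be PlantedEffect")
  if (length(msg)) msg else TRUE
})

#' @rdname CohortConfig-class
#' @param nParticipants,nSessions,runsPerSession,runDurationS,fsNfb,fsEeg,eegDurationS,nChannels,gridShape,nVolumes,trS,voxelSizeMm,nRois,roiRadiusMm,effects,slopeMean,slopeSd,basePower,powerFloor,nfbNoiseSd,seed
#'   see slots.
#' @export
cohortConfig <- function(nParticipants = 27, nSessions = 3,
                         runsPerSession = 12, runDurationS = 180, fsNfb = 250,
                         fsEeg = 1000, eegDurationS = 180, nChannels = 64,
                         gridShape = c(16L, 16L, 16L), nVolumes = 100,
                         trS = 2.0, voxelSizeMm = 3, nRois = 20,
                         roiRadiusMm = 8, effects = list(),
                         slopeMean = 0.02, slopeSd = 0.04,
                         basePower = 1.0, powerFloor = 0.05,
                         nfbNoiseSd = 0.3, seed = 1L) {
  new("CohortConfig",
      nParticipants = as.integer(nParticipants),
      nSessions = as.integer(nSessions),
      runsPerSession = as.integer(runsPerSession),
      runDurationS = runDurationS, fsNfb = fsNfb, fsEeg = fsEeg,
      eegDurationS = eegDurationS, nChannels = as.integer(nChannels),
      gridShape = as.integer(gridShape), nVolumes = as.integer(nVolumes),
      trS = trS, voxelSizeMm = voxelSizeMm, nRois = as.integer(nRois),
      roiRadiusMm = roiRadiusMm, effects = effects, slopeMean = slopeMean,
      slopeSd = slopeSd, basePower = basePower, powerFloor = powerFloor,
      nfbNoiseSd = nfbNoiseSd, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# CohortDataset
# ---------------------------------------------------------------------------

#' A synthetic multimodal cohort
#'
#' Per-participant bundle of NFB training runs, resting EEG recordings, an
#' fMRI 4D volume, morphometry maps, covariates and — for synthetic cohorts
#' only — the generator's ground truth. Ground truth is write-only for the
#' analysis stages: no analysis function in the package accepts it.
#'
#' @slot nfb list (one per participant) of lists (one per session) of raw NFB
#'   run signals; each run is a numeric vector at `fsNfb` Hz, run index 0
#'   first (the baseline run).
#' @slot eeg list per participant: `list(eo=, ec=)` channel-by-sample matrices
#'   with channel rownames (may be empty if the modality was not generated).
#' @slot fmri list per participant of 4D arrays (x, y, z, t).
#' @slot gmv,wmv lists per participant of 3D maps.
#' @slot mask logical 3D array (shared brain mask).
#' @slot roiTable data.frame: name, x, y, z (mm), radius (mm), network.
#' @slot covariates data.frame: id, age, sex.
#' @slot config the generating \linkS4class{CohortConfig}.
#' @slot groundTruth list: `trueSlope` per participant, `latent`
#'   (participants x effects, noise-free), `latentObserved` (with feature
#'   noise).
#' @export
setClass("CohortDataset", representation(
  nfb = "list", eeg = "list", fmri = "list", gmv = "list", wmv = "list",
  mask = "array", roiTable = "data.frame", covariates = "data.frame",
  config = "CohortConfig", groundTruth = "list"
))

#' @export
setMethod("show", "CohortDataset", function(object) {
  cfg <- object@config
  cat("CohortDataset:", cfg@nParticipants, "participants,",
      cfg@nSessions, "sessions x", cfg@runsPerSession, "runs\n")
  cat("  modalities present:",
      paste(c("nfb", "eeg", "fmri", "gmv", "wmv")[
        c(length(object@nfb), length(object@eeg), length(object@fmri),
          length(object@gmv), length(object@wmv)) > 0], collapse = ", "),
      "\n")
  cat("  planted effects:", length(cfg@effects), "\n")
})

#' Cohort accessors
#'
#' @param object a \linkS4class{CohortDataset}.
#' @return `covariates()` the covariate data.frame; `groundTruth()` the
#'   generator ground-truth list; `cohortConfigOf()` the generating config.
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))
#' @rdname covariates
#' @export
setMethod("covariates", "CohortDataset", function(object) object@covariates)

#' @rdname covariates
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname covariates
#' @export
setMethod("groundTruth", "CohortDataset", function(object) object@groundTruth)

#' @rdname covariates
#' @export
setGeneric("cohortConfigOf", function(object) standardGeneric("cohortConfigOf"))
#' @rdname covariates
#' @export
setMethod("cohortConfigOf", "CohortDataset", function(object) object@config)

# ---------------------------------------------------------------------------
# StatMap
# ---------------------------------------------------------------------------

#' Voxelwise permutation GLM result
#'
#' @slot tmap 3D array of (pseudo-)t statistics for the learning-index
#'   regressor.
#' @slot pmap 3D array of two-sided permutation p-values.
#' @slot clusters 3D integer array: 0 outside significant clusters, positive
#'   labels for positive-contrast clusters, negative labels for
#'   negative-contrast clusters.
#' @slot clusterTable data.frame: label, sign, size, peak voxel indices, peak
#'   statistic.
#' @slot settings list echoing voxelP, minCluster, nPerm, connectivity.
#' @export
setClass("StatMap", representation(
  tmap = "array", pmap = "array", clusters = "array",
  clusterTable = "data.frame", settings = "list"
))

#' @export
setMethod("show", "StatMap", function(object) {
  ct <- object@clusterTable
  cat("StatMap:", paste(dim(object@tmap), collapse = "x"), "grid,",
      object@settings$nPerm, "permutations\n")
  cat("  clusters kept (size >", object@settings$minCluster, "):",
      nrow(ct), "\n")
  if (nrow(ct)) print(ct)
})

#' @rdname StatMap-class
#' @param object a StatMap.
#' @export
setGeneric("clusterTable", function(object) standardGeneric("clusterTable"))
#' @rdname StatMap-class
#' @export
setMethod("clusterTable", "StatMap", function(object) object@clusterTable)

# ---------------------------------------------------------------------------
# FeatureSet / PredictionReport
# ---------------------------------------------------------------------------

#' A screened feature set for prediction
#'
#' @slot name one of `"eeg"`, `"smri"`, `"alff"`, `"fc"`, `"multimodal"`.
#' @slot x participants-by-features numeric matrix (z-scored columns).
#' @slot provenance character vector describing the origin of each column.
#' @slot degenerate logical; TRUE when the modality had no selected feature
#'   and a flagged fallback column is used.
#' @export
setClass("FeatureSet", representation(
  name = "character", x = "matrix", provenance = "character",
  degenerate = "logical"
))

setValidity("FeatureSet", function(object) {
  if (!all(is.finite(object@x))) return("feature matrix must be finite")
  if (ncol(object@x) != length(object@provenance))
    return("one provenance entry per column required")
  TRUE
})

#' @export
setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet '", object@name, "': ", nrow(object@x), " participants x ",
      ncol(object@x), " features",
      if (object@degenerate) " [degenerate fallback]", "\n", sep = "")
})

#' Leave-one-out prediction report
#'
#' @slot scores data.frame: featureSet, model, mae, r.
#' @slot predictions named list of per-participant predicted LI vectors
#'   (names `<set>.<model>`).
#' @slot comparisons data.frame of Steiger z tests of each single-modality
#'   correlation against the multimodal correlation (same model).
#' @slot li the actual (normalised) learning-index vector.
#' @export
setClass("PredictionReport", representation(
  scores = "data.frame", predictions = "list", comparisons = "data.frame",
  li = "numeric"
))

#' @export
setMethod("show", "PredictionReport", function(object) {
  cat("PredictionReport over", length(object@li), "participants\n")
  print(object@scores, row.names = FALSE)
  if (nrow(object@comparisons)) {
    cat("Dependent-correlation comparisons vs multimodal:\n")
    print(object@comparisons, row.names = FALSE)
  }
})

#' @rdname PredictionReport-class
#' @param object a PredictionReport.
#' @export
setGeneric("predictionScores", function(object) standardGeneric("predictionScores"))
#' @rdname PredictionReport-class
#' @export
setMethod("predictionScores", "PredictionReport", function(object) object@scores)
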