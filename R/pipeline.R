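# End-to-end orchestration: learning indices -> baseline features ->
# screening -> prediction.

#' Extract resting-EEG features for a cohort
#'
#' Preprocesses each recording ([preprocessResting()]) and computes the
#' scalp-ROI relative band-power table ([roiBandTable()]) per eye condition.
#'
#' @param cohort a \linkS4class{CohortDataset} with the `eeg` modality.
#' @param bands a [bandScheme()].
#' @param roiMap ROI-channel map (default [scalpRoiMap()]).
#' @return participants-by-features matrix, columns named
#'   `<condition>.<roi>.<band>`.
#' @export
extractEegFeatures <- function(cohort, bands = bandScheme(),
                               roiMap = scalpRoiMap()) {
  stopifnot(length(cohort@eeg) > 0L)
  fs <- cohort@config@fsEeg
  rows <- lapply(cohort@eeg, function(rec) {
    unlist(lapply(names(rec), function(cond) {
      ep <- preprocessResting(rec[[cond]], fs,
                              band = attr(bands, "fullBand"))
      tb <- roiBandTable(ep, fs, roiMap = roiMap, bands = bands)
      v <- as.vector(tb)
      names(v) <- paste(cond, rep(rownames(tb), ncol(tb)),
                        rep(colnames(tb), each = nrow(tb)), sep = ".")
      v
    }))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- cohort@covariates$id[seq_len(nrow(m))]
  m
}

#' Extract resting-fMRI features for a cohort
#'
#' Implements the standard regional-metric paths: ALFF and fALFF on the
#' spatially smoothed, unfiltered series; ReHo on the band-passed,
#' unsmoothed series with the resulting map z-standardised then smoothed;
#' ALFF/fALFF maps z-standardised; ROI-sphere mean series from the
#' band-passed data and their Fisher-z connectivity matrix.
#'
#' @param cohort a \linkS4class{CohortDataset} with the `fmri` modality.
#' @param alffBand low-frequency band for ALFF/fALFF, Hz.
#' @param smoothFwhmMm spatial smoothing FWHM, mm.
#' @return list: `alff`, `falff`, `reho` (lists of z-standardised 3D maps),
#'   `fc` (list of connectome matrices), `edges` (participants-by-edges
#'   matrix).
#' @export
extractFmriFeatures <- function(cohort, alffBand = c(0.01, 0.08),
                                smoothFwhmMm = 6) {
  stopifnot(length(cohort@fmri) > 0L)
  cfg <- cohort@config
  mask <- cohort@mask
  vs <- cfg@voxelSizeMm
  res <- lapply(cohort@fmri, function(vol) {
    d <- dim(vol)
    sm <- gaussianSmooth(vol, smoothFwhmMm, vs)
    flatSm <- t(matrix(sm, prod(d[1:3]), d[4]))[, as.vector(mask),
                                                drop = FALSE]
    aMap <- array(0, d[1:3]); aMap[mask] <- alff(flatSm, cfg@trS, alffBand)
    fMap <- array(0, d[1:3]); fMap[mask] <- falff(flatSm, cfg@trS, alffBand)
    flat <- t(matrix(vol, prod(d[1:3]), d[4]))
    bp <- bandpassTimeseries(flat, cfg@trS)
    bpVol <- array(t(bp), d)
    rMap <- gaussianSmooth(zStandardizeMap(reho(bpVol, mask), mask),
                           smoothFwhmMm, vs)
    roiSeries <- extractRoiSeries(bpVol, cohort@roiTable, mask, vs)
    list(alff = zStandardizeMap(aMap, mask),
         falff = zStandardizeMap(fMap, mask),
         reho = rMap, fc = fcMatrix(roiSeries))
  })
  list(alff = lapply(res, `[[`, "alff"),
       falff = lapply(res, `[[`, "falff"),
       reho = lapply(res, `[[`, "reho"),
       fc = lapply(res, `[[`, "fc"),
       edges = do.call(rbind, lapply(res, function(r) edgeVector(r$fc))))
}

#' Screen all modalities for learning-index correlates
#'
#' EEG ROI/band cells: Spearman + Benjamini-Hochberg ([spearmanScreen()]).
#' GMV, WMV and the three regional fMRI maps: permutation GLM with age and
#' sex covariates ([permutationGlmMap()]). FC edges: partial Spearman at
#' p < 0.005 ([edgeScreen()]).
#'
#' @param li learning-index vector.
#' @param covariates data.frame with `age` and `sex`.
#' @param eegFeatures matrix from [extractEegFeatures()] (or NULL).
#' @param fmriFeatures list from [extractFmriFeatures()] (or NULL).
#' @param gmv,wmv lists of morphometry maps (or NULL).
#' @param mask logical 3D array.
#' @param nPerm permutations for the voxelwise GLMs.
#' @param alpha EEG FDR level.
#' @param edgeP FC edge threshold.
#' @param voxelP,minCluster voxelwise GLM thresholds.
#' @return list of screening results (`eeg`, `gmv`, `wmv`, `alff`, `falff`,
#'   `reho`, `fc`); map entries are \linkS4class{StatMap}s.
#' @export
screenCohort <- function(li, covariates, eegFeatures = NULL,
                         fmriFeatures = NULL, gmv = NULL, wmv = NULL,
                         mask = NULL, nPerm = 1000L, alpha = 0.05,
                         edgeP = 0.005, voxelP = 0.005, minCluster = 50L) {
  cov2 <- covariates[, c("age", "sex"), drop = FALSE]
  out <- list()
  if (!is.null(eegFeatures))
    out$eeg <- spearmanScreen(eegFeatures, li, alpha = alpha)
  mapScreen <- function(maps) permutationGlmMap(
    maps, li, cov2, mask, nPerm = nPerm, voxelP = voxelP,
    minCluster = minCluster)
  if (!is.null(gmv) && length(gmv)) out$gmv <- mapScreen(gmv)
  if (!is.null(wmv) && length(wmv)) out$wmv <- mapScreen(wmv)
  if (!is.null(fmriFeatures)) {
    out$alff <- mapScreen(fmriFeatures$alff)
    out$falff <- mapScreen(fmriFeatures$falff)
    out$reho <- mapScreen(fmriFeatures$reho)
    out$fc <- edgeScreen(fmriFeatures$edges, li, cov2, pThresh = edgeP)
  }
  out
}

# Per-participant mean map value inside each kept cluster of a StatMap.
clusterMeans <- function(maps, statMap, prefix) {
  ct <- clusterTable(statMap)
  if (!nrow(ct)) return(matrix(0, length(maps), 0))
  cols <- vapply(seq_len(nrow(ct)), function(i) {
    vox <- which(statMap@clusters == ct$label[i])
    vapply(maps, function(m) mean(m[vox]), numeric(1))
  }, numeric(length(maps)))
  cols <- matrix(cols, nrow = length(maps))
  colnames(cols) <- paste0(prefix, ".cluster", seq_len(nrow(ct)))
  cols
}

#' Assemble the screened prediction feature sets for a cohort
#'
#' Selected EEG cells, significant GMV/WMV cluster means, significant
#' regional-fMRI (ALFF path) cluster means and selected FC edges, handed to
#' [assembleFeatures()]. Modalities with no selected feature fall back to
#' their best-ranked single feature, flagged degenerate.
#'
#' @param screens output of [screenCohort()].
#' @param li learning-index vector.
#' @param eegFeatures,fmriFeatures,gmv,wmv the feature stores used during
#'   screening.
#' @return output of [assembleFeatures()].
#' @export
assembleCohortFeatures <- function(screens, li, eegFeatures = NULL,
                                   fmriFeatures = NULL, gmv = NULL,
                                   wmv = NULL) {
  sets <- list(); fallback <- list()
  if (!is.null(screens$eeg)) {
    sel <- screens$eeg$selected
    sets$eeg <- eegFeatures[, sel, drop = FALSE]
    best <- which.min(screens$eeg$p)
    fallback$eeg <- eegFeatures[, best, drop = FALSE]
  }
  if (!is.null(screens$gmv) || !is.null(screens$wmv)) {
    cols <- cbind(
      if (!is.null(screens$gmv)) clusterMeans(gmv, screens$gmv, "gmv"),
      if (!is.null(screens$wmv)) clusterMeans(wmv, screens$wmv, "wmv"))
    sets$smri <- cols
    fallback$smri <- bestVoxelFallback(list(gmv = list(maps = gmv,
                                                       sm = screens$gmv),
                                            wmv = list(maps = wmv,
                                                       sm = screens$wmv)))
  }
  if (!is.null(screens$alff)) {
    regional <- cbind(
      clusterMeans(fmriFeatures$alff, screens$alff, "alff"),
      clusterMeans(fmriFeatures$falff, screens$falff, "falff"),
      clusterMeans(fmriFeatures$reho, screens$reho, "reho"))
    sets$alff <- regional
    fallback$alff <- bestVoxelFallback(list(alff = list(
      maps = fmriFeatures$alff, sm = screens$alff)))
  }
  if (!is.null(screens$fc)) {
    sel <- screens$fc$selected
    sets$fc <- fmriFeatures$edges[, sel, drop = FALSE]
    best <- which.min(screens$fc$p)
    fallback$fc <- fmriFeatures$edges[, best, drop = FALSE]
  }
  assembleFeatures(sets, li, fallback = fallback)
}

# Fallback column for a map modality with no surviving cluster: the value at
# the voxel with the largest |t|.
bestVoxelFallback <- function(entries) {
  entries <- Filter(function(e) !is.null(e$sm), entries)
  best <- NULL; bestT <- -Inf; bestName <- ""
  for (nm in names(entries)) {
    tm <- entries[[nm]]$sm@tmap
    v <- which.max(abs(tm))
    if (abs(tm[v]) > bestT) {
      bestT <- abs(tm[v])
      best <- vapply(entries[[nm]]$maps, function(m) m[v], numeric(1))
      bestName <- paste0(nm, ".peakVoxel")
    }
  }
  m <- matrix(best, ncol = 1L)
  colnames(m) <- bestName
  m
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages: learning indices from the online feedback engine; baseline
#' feature extraction (resting EEG, fMRI, morphometry); screening;
#' assembly of the screened feature sets; leave-one-out prediction.
#' Deterministic given the cohort and `seed`. Modalities absent from the
#' cohort are skipped with a warning and prediction is restricted to the
#' available sets.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param feedbackCfg a \linkS4class{FeedbackConfig}.
#' @param nPerm permutations for voxelwise GLMs.
#' @param models prediction models (see [loocvPredict()]).
#' @param seed integer seed for stochastic models.
#' @param outDir optional directory: writes the feature table (TSV), the
#'   screening stat-map NIfTIs, the prediction report (JSON) and a run log.
#' @return list: `li` (cohort learning-index result), `eegFeatures`,
#'   `fmriFeatures`, `screens`, `featureSets`, `report`
#'   (\linkS4class{PredictionReport}).
#' @export
runPipeline <- function(cohort, feedbackCfg = feedbackConfig(),
                        nPerm = 1000L, models = "svr_linear", seed = 1L,
                        outDir = NULL) {
  stopifnot(is(cohort, "CohortDataset"))
  if (!length(cohort@nfb))
    stop("cohort has no NFB runs; the learning index cannot be computed")
  liRes <- cohortLearningIndex(cohort, feedbackCfg)
  li <- liRes$li
  eegF <- if (length(cohort@eeg)) extractEegFeatures(cohort) else {
    warning("no EEG modality; skipping"); NULL
  }
  fmriF <- if (length(cohort@fmri)) extractFmriFeatures(cohort) else {
    warning("no fMRI modality; skipping"); NULL
  }
  gmv <- if (length(cohort@gmv)) cohort@gmv else NULL
  wmv <- if (length(cohort@wmv)) cohort@wmv else NULL
  screens <- screenCohort(li, cohort@covariates, eegFeatures = eegF,
                          fmriFeatures = fmriF, gmv = gmv, wmv = wmv,
                          mask = cohort@mask, nPerm = nPerm)
  assembled <- assembleCohortFeatures(screens, li, eegFeatures = eegF,
                                      fmriFeatures = fmriF, gmv = gmv,
                                      wmv = wmv)
  report <- predictLearning(assembled, models = models, seed = seed)
  out <- list(li = liRes, eegFeatures = eegF, fmriFeatures = fmriF,
              screens = screens, featureSets = assembled, report = report)
  if (!is.null(outDir)) writePipelineOutputs(out, cohort, outDir, seed)
  out
}

writePipelineOutputs <- function(out, cohort, outDir, seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  li <- out$li$li
  utils::write.table(
    data.frame(id = names(li), li = li),
    file.path(outDir, "learning_index.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  if (!is.null(out$eegFeatures))
    utils::write.table(
      data.frame(id = rownames(out$eegFeatures), out$eegFeatures,
                 check.names = FALSE),
      file.path(outDir, "eeg_features.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
  vs <- cohort@config@voxelSizeMm
  for (nm in intersect(names(out$screens),
                       c("gmv", "wmv", "alff", "falff", "reho"))) {
    sm <- out$screens[[nm]]
    writeVolume(sm@tmap, file.path(outDir, paste0(nm, "_tmap.nii.gz")), vs)
    writeVolume(sm@clusters * 1.0,
                file.path(outDir, paste0(nm, "_clusters.nii.gz")), vs)
  }
  rep <- out$report
  jsonlite::write_json(
    list(seed = seed, scores = rep@scores, comparisons = rep@comparisons,
         predictions = rep@predictions, li = rep@li),
    file.path(outDir, "prediction_report.json"), digits = NA,
    dataframe = "rows", auto_unbox = TRUE)
  writeLines(c(paste("nfblearn", as.character(utils::packageVersion("nfblearn"))),
               paste("seed", seed), paste("run", format(Sys.time()))),
             file.path(outDir, "run_log.txt"))
  invisible(outDir)
}
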