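# File formats: delimited EEG matrices with channel sidecars, NIfTI-1
# volumes, TSV tables, JSON ground truth.

#' Read a multichannel EEG recording
#'
#' Reads a plain or gzip-compressed delimited numeric matrix (samples in
#' columns, one row per channel) together with its `channels.tsv` sidecar
#' (columns `name` and `fs`). Plain and gzip files yield identical arrays.
#'
#' @param path path to the `.csv` or `.csv.gz` matrix.
#' @param sidecar path to the channel sidecar; defaults to `channels.tsv`
#'   next to `path`.
#' @return list: `signal` (channels-by-samples matrix with rownames), `fs`.
#' @export
readEeg <- function(path, sidecar = file.path(dirname(path), "channels.tsv")) {
  if (!file.exists(sidecar))
    stop("channel sidecar not found: ", sidecar)
  meta <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  if (!all(c("name", "fs") %in% names(meta)))
    stop("sidecar must have 'name' and 'fs' columns")
  if (anyDuplicated(meta$name))
    stop("duplicate channel names in sidecar")
  fs <- unique(meta$fs)
  if (length(fs) != 1L || !is.finite(fs))
    stop("sidecar must give a single finite sampling rate")
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  m <- as.matrix(utils::read.csv(con, header = FALSE))
  dimnames(m) <- list(meta$name, NULL)
  if (nrow(m) != nrow(meta))
    stop("matrix has ", nrow(m), " rows but sidecar lists ", nrow(meta),
         " channels")
  list(signal = m, fs = fs)
}

#' Write a multichannel EEG recording
#'
#' @param signal channels-by-samples matrix with channel rownames.
#' @param fs sampling rate, Hz.
#' @param path output `.csv` or `.csv.gz` path.
#' @param sidecar sidecar path (default `channels.tsv` next to `path`).
#' @return `path`, invisibly.
#' @export
writeEeg <- function(signal, fs, path,
                     sidecar = file.path(dirname(path), "channels.tsv")) {
  stopifnot(is.matrix(signal), !is.null(rownames(signal)))
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  utils::write.table(signal, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(name = rownames(signal), fs = fs), sidecar,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NIfTI volume (3D or 4D)
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param expect `"any"`, `"3d"` or `"4d"`.
#' @return list: `data` (array), `tr` (seconds, from pixdim\[4\]; NA for 3D),
#'   `voxelSizeMm` (first spatial pixdim).
#' @export
readVolume <- function(path, expect = c("any", "3d", "4d")) {
  expect <- match.arg(expect)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (expect == "4d" && nd != 4L)
    stop("expected a 4D volume but '", path, "' has ", nd, " dimensions")
  if (expect == "3d" && nd != 3L)
    stop("expected a 3D volume but '", path, "' has ", nd, " dimensions")
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr,
       tr = if (nd == 4L) pd[4] else NA_real_,
       voxelSizeMm = pd[1])
}

#' Write a NIfTI volume
#'
#' @param data 3D or 4D numeric array.
#' @param path output path (`.nii.gz`).
#' @param voxelSizeMm isotropic voxel size.
#' @param tr repetition time for 4D data, seconds.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(data, path, voxelSizeMm = 3, tr = NA_real_) {
  img <- RNifti::asNifti(data)
  pd <- rep(1, length(dim(data)))
  pd[1:3] <- voxelSizeMm
  if (length(dim(data)) == 4L && is.finite(tr)) pd[4] <- tr
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI definition table
#'
#' TSV with columns name, x, y, z (mm), radius (mm, optional, default 8) and
#' network.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readRoiTable <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(tb)))
    stop("ROI table must have columns ", paste(need, collapse = ", "))
  if (!"radius" %in% names(tb)) tb$radius <- 8
  tb
}

#' Read a participant covariate table
#'
#' TSV with columns id, age, sex.
#'
#' @param path TSV path.
#' @return data.frame with `sex` as a factor.
#' @export
readCovariates <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "age", "sex") %in% names(tb)))
    stop("covariate table must have columns id, age, sex")
  tb$sex <- factor(tb$sex)
  tb
}

#' Write a cohort to disk
#'
#' EEG recordings as csv.gz + channels.tsv, volumes as NIfTI-1, tables as
#' TSV, ground truth as JSON — the on-disk layout [runPipeline()] can consume.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort@config
  utils::write.table(cohort@covariates, file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort@roiTable, file.path(dir, "rois.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (p in seq_along(cohort@eeg)) {
    pd <- file.path(dir, cohort@covariates$id[p], "eeg")
    dir.create(pd, recursive = TRUE, showWarnings = FALSE)
    for (cond in names(cohort@eeg[[p]]))
      writeEeg(cohort@eeg[[p]][[cond]], cfg@fsEeg,
               file.path(pd, paste0("rest_", cond, ".csv.gz")),
               sidecar = file.path(pd, paste0("channels_", cond, ".tsv")))
  }
  for (p in seq_along(cohort@fmri))
    writeVolume(cohort@fmri[[p]],
                file.path(dir, cohort@covariates$id[p], "func.nii.gz"),
                voxelSizeMm = cfg@voxelSizeMm, tr = cfg@trS)
  for (p in seq_along(cohort@gmv)) {
    writeVolume(cohort@gmv[[p]],
                file.path(dir, cohort@covariates$id[p], "gmv.nii.gz"),
                voxelSizeMm = cfg@voxelSizeMm)
    writeVolume(cohort@wmv[[p]],
                file.path(dir, cohort@covariates$id[p], "wmv.nii.gz"),
                voxelSizeMm = cfg@voxelSizeMm)
  }
  jsonlite::write_json(cohort@groundTruth[c("trueSlope")],
                       file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}
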