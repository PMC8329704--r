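# Online feedback computation and the within-session learning index.

#' Sliding-window SMR band power
#'
#' Computes the online feedback quantity: the signal is (optionally) band-pass
#' filtered to the online band, then an FFT is taken over a sliding window
#' (default 10 s, stepped every 100 ms, rectangular taper) and the one-sided
#' periodogram is summed over all bins whose centre frequency falls inside the
#' SMR band (endpoints inclusive). The window is causal: the first power value
#' corresponds to the window ending `windowS` seconds into the run, so a run
#' of duration D yields `floor((D - windowS)/stepS) + 1` values.
#'
#' Power is scaled so a pure sinusoid of amplitude A at a bin frequency inside
#' the band yields A^2/2; scaling the raw signal by c scales every power by
#' c^2.
#'
#' @param signal numeric vector, the raw feedback-channel samples.
#' @param cfg a \linkS4class{FeedbackConfig}.
#' @return numeric vector of band-power values, one per window position.
#' @examples
#' cfg <- feedbackConfig(windowS = 2, prefilter = FALSE)
#' t <- seq(0, 4, by = 1/250)[-1]
#' p <- onlineSmrPower(sin(2 * pi * 13.5 * t), cfg)
#' all.equal(median(p), 0.5, tolerance = 1e-6)
#' @export
onlineSmrPower <- function(signal, cfg = feedbackConfig()) {
  stopifnot(is.numeric(signal), all(is.finite(signal)))
  win <- round(cfg@windowS * cfg@fs)
  step <- round(cfg@stepS * cfg@fs)
  if (length(signal) < win)
    stop("signal (", length(signal), " samples) shorter than one analysis ",
         "window (", win, " samples)")
  if (cfg@prefilter)
    signal <- butterBandpass(signal, cfg@fs, cfg@onlineBand[1],
                             cfg@onlineBand[2])
  taper <- if (cfg@taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / win)
  } else rep(1, win)
  # Band bins of the one-sided spectrum (0-based index k -> k*fs/win Hz)
  freqs <- (seq_len(win %/% 2 + 1) - 1) * cfg@fs / win
  inBand <- freqs >= cfg@smrBand[1] & freqs <= cfg@smrBand[2]
  starts <- seq(1L, length(signal) - win + 1L, by = step)
  # All windows as columns; mvfft keeps this a single vectorised FFT call.
  w <- matrix(signal[outer(seq_len(win) - 1L, starts, `+`)], nrow = win)
  X <- stats::mvfft(w * taper)[seq_along(freqs), , drop = FALSE]
  colSums((2 / win^2) * Mod(X[inBand, , drop = FALSE])^2)
}

#' Adaptive threshold from the previous run
#'
#' The feedback threshold for a run is the median online SMR power of the
#' preceding run; the baseline run (index 0) seeds the initial individual
#' threshold.
#'
#' @param previousRunPowers numeric vector of the previous run's online power
#'   values.
#' @return the median power.
#' @export
adaptThreshold <- function(previousRunPowers) {
  if (length(previousRunPowers) == 0L)
    stop("cannot adapt threshold from an empty power series")
  stats::median(previousRunPowers)
}

#' Reward scoring
#'
#' One point per maximal above-threshold stretch whose duration (number of
#' steps times the step length) strictly exceeds the hold requirement; a
#' stretch yields exactly one point regardless of how much longer it lasts.
#'
#' @param powers online power series (one value per `stepS`).
#' @param threshold power threshold.
#' @param cfg a \linkS4class{FeedbackConfig} (supplies `stepS`,
#'   `rewardHoldS`).
#' @return integer reward count.
#' @export
scoreRewards <- function(powers, threshold, cfg = feedbackConfig()) {
  stopifnot(is.numeric(powers), is.numeric(threshold), length(threshold) == 1L)
  if (!length(powers)) return(0L)
  r <- rle(powers > threshold)
  sum(r$values & r$lengths * cfg@stepS > cfg@rewardHoldS)
}

#' Summarise one training run
#'
#' @param signal raw feedback-channel samples for the run.
#' @param runIndex 0-based run index (0 = baseline).
#' @param threshold threshold in force during the run (median power of the
#'   previous run), or `NA` for the baseline run.
#' @param cfg a \linkS4class{FeedbackConfig}.
#' @return one-row data.frame: runIndex, medianSmrPower, thresholdUsed,
#'   rewardPoints, nWindows.
#' @export
summarizeRun <- function(signal, runIndex, threshold = NA_real_,
                         cfg = feedbackConfig()) {
  p <- onlineSmrPower(signal, cfg)
  data.frame(
    runIndex = runIndex,
    medianSmrPower = stats::median(p),
    thresholdUsed = threshold,
    rewardPoints = if (is.na(threshold)) NA_integer_
                   else scoreRewards(p, threshold, cfg),
    nWindows = length(p))
}

#' Within-session learning index
#'
#' For each session, an ordinary least-squares regression of the run-median
#' SMR powers on the 0-based run index; the learning index (LI) is the mean of
#' the per-session slopes. Slope units are power per run.
#'
#' @param sessionRunMedians list with one numeric vector of run medians per
#'   session (equal lengths, at least 2 runs each).
#' @param includeBaseline logical; include the baseline run (index 0) in the
#'   regression (default TRUE, regressing over all runs). When FALSE the first
#'   median of each session is dropped and the remaining runs keep their
#'   original indices 1, 2, ...
#' @return list of class `LearningResult`: `sessionSlopes`, `li`,
#'   `runMedians` (the input), `includeBaseline`.
#' @examples
#' learningIndex(list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4)))$li  # 1
#' @export
learningIndex <- function(sessionRunMedians, includeBaseline = TRUE) {
  stopifnot(is.list(sessionRunMedians), length(sessionRunMedians) >= 1L)
  lens <- lengths(sessionRunMedians)
  if (length(unique(lens)) != 1L)
    stop("sessions must have equal run counts")
  slopes <- vapply(sessionRunMedians, function(m) {
    if (any(!is.finite(m))) stop("non-finite run medians")
    idx <- seq_along(m) - 1
    if (!includeBaseline) { m <- m[-1L]; idx <- idx[-1L] }
    if (length(m) < 2L) stop("need at least 2 run medians per session")
    # closed-form OLS slope; exact on noiseless linear input
    sum((idx - mean(idx)) * (m - mean(m))) / sum((idx - mean(idx))^2)
  }, numeric(1))
  structure(list(sessionSlopes = slopes, li = mean(slopes),
                 runMedians = sessionRunMedians,
                 includeBaseline = includeBaseline),
            class = "LearningResult")
}

#' @export
print.LearningResult <- function(x, ...) {
  cat("LearningResult: LI =", format(x$li), "(",
      length(x$sessionSlopes), "session slopes:",
      paste(format(x$sessionSlopes, digits = 4), collapse = ", "), ")\n")
  invisible(x)
}

#' Cohort-level learning indices
#'
#' Runs the full online pipeline for every participant of a cohort: per run,
#' the online SMR power series and its median; per session, thresholds adapted
#' from the previous run's median and reward points; per participant, the
#' learning index. Also reports the Shapiro-Wilk normality p-value of LI
#' across the cohort (the distributional check that motivates rank-based
#' screening downstream).
#'
#' @param cohort a \linkS4class{CohortDataset} with the `nfb` modality.
#' @param cfg a \linkS4class{FeedbackConfig}.
#' @param includeBaseline passed to [learningIndex()].
#' @return list: `li` (named numeric per participant), `results` (list of
#'   `LearningResult`), `runs` (data.frame of per-run summaries),
#'   `normalityP` (Shapiro-Wilk p across participants, NA for n < 3).
#' @export
cohortLearningIndex <- function(cohort, cfg = feedbackConfig(),
                                includeBaseline = TRUE) {
  stopifnot(is(cohort, "CohortDataset"), length(cohort@nfb) > 0L)
  runRows <- list()
  results <- lapply(seq_along(cohort@nfb), function(p) {
    sessions <- cohort@nfb[[p]]
    medians <- lapply(seq_along(sessions), function(s) {
      thr <- NA_real_
      meds <- numeric(length(sessions[[s]]))
      for (r in seq_along(sessions[[s]])) {
        pow <- onlineSmrPower(sessions[[s]][[r]], cfg)
        meds[r] <- stats::median(pow)
        runRows[[length(runRows) + 1L]] <<- data.frame(
          participant = p, session = s, runIndex = r - 1L,
          medianSmrPower = meds[r], thresholdUsed = thr,
          rewardPoints = if (is.na(thr)) NA_integer_
                         else scoreRewards(pow, thr, cfg),
          nWindows = length(pow))
        thr <- adaptThreshold(pow)
      }
      meds
    })
    learningIndex(medians, includeBaseline = includeBaseline)
  })
  li <- vapply(results, `[[`, numeric(1), "li")
  names(li) <- cohort@covariates$id[seq_along(li)]
  normP <- if (length(li) >= 3L && stats::sd(li) > 0)
    stats::shapiro.test(li)$p.value else NA_real_
  list(li = li, results = results, runs = do.call(rbind, runRows),
       normalityP = normP)
}
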