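---
title: "nfblearn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nfblearn: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
what is computed, under which assumptions, which parameters matter, and
where a genuinely open design point was settled one way rather than
another. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The feedback engine and the learning index

The quantity fed back to a participant in SMR up-regulation training is the
12–15 Hz band power of a single sensorimotor channel, recomputed every
100 ms from the trailing 10 s of signal. `onlineSmrPower()` implements this
as: optional zero-phase Butterworth band-pass to the online band
(0.5–45 Hz), then for each window position the FFT of the raw (rectangular)
window and the sum of the one-sided periodogram over all bins whose centre
frequency lies in [12, 15] Hz, endpoints inclusive. The scaling is chosen so
that a sinusoid of amplitude $A$ at a bin frequency contributes $A^2/2$;
consequently the whole engine is scale-equivariant (scaling the signal by
$c$ scales powers and the learning index by $c^2$), which the tests assert.

Choices worth making explicit:

* **Taper.** No taper is applied by default (a `hann` option exists). A
  10-s rectangular window at 250 Hz has 0.1 Hz bin spacing and sidelobe
  leakage far below the 1 % out-of-band bound the tests enforce; the
  rectangular choice is also the most literal reading of "an FFT of the
  data window".
* **Prefilter gain.** The zero-phase Butterworth pass-band gain differs
  from 1 by ~1e-4. That is irrelevant in practice but matters to
  exact-recovery tests, so `prefilter = FALSE` is available and used
  whenever a test asserts 1e-9 agreement.
* **Threshold adaptation** (`adaptThreshold()`) is the median of the
  previous run's online power series; the baseline run (index 0) seeds the
  initial threshold.
* **Reward scoring** (`scoreRewards()`) grants exactly one point per
  maximal above-threshold stretch strictly longer than 1 s. Whether a very
  long stretch should re-trigger further points is not defined by the
  protocol description; one-point-per-stretch is the simplest consistent
  rule and is stated in the function contract.

**Learning index.** Per session, the run-median powers are regressed by
ordinary least squares on the 0-based run index; `LI` is the mean slope
across sessions (power per run). Session run counts are commonly described
both as "10 runs" and as "all 12 training runs" in this literature; the
generator and `learningIndex()` therefore take `runsPerSession` as a
parameter (default 12, run 0 being the no-trend baseline run) and a flag
controls whether the baseline run enters the regression (default yes,
matching "all training runs"). Changing either only rescales slopes; no
test depends on the distinction. Whether real learners follow a linear or
saturating trajectory is unknown; linear is assumed because the index
itself is a regression slope.

## 2. Resting-EEG features

`preprocessResting()` band-passes 1–100 Hz, re-references to the **common
average** (the phrase "a common reference" admits several readings;
common-average is the only parameter-free standard one) and cuts
non-overlapping 1-s epochs. ICA-based artifact removal belongs to
interactive preprocessing of human recordings and is out of scope; an
amplitude-based epoch rejector can be emulated by dropping epochs before
`roiBandTable()`.

`welchPsd()` uses 1000-point segments, 50 % overlap and a Hamming taper,
one-sided density scaling (the PSD integrates to the variance). Relative
band power is the band integral over the full-band integral; the "full
band" is not numerically pinned down by convention, so the denominator
defaults to the 1–100 Hz preprocessing band and is configurable.

**Standardisation of epoch powers.** The per-run value of a channel × band
cell is: relative power per epoch, z-standardised, median across epochs,
then the mean over the ROI's channels. The standardisation is computed
*jointly over all epochs and channels* of the recording (per band). The
per-channel alternative — z-scoring each channel across its own epochs —
makes the subsequent median a level-free, skewness-like statistic and
destroys exactly the between-participant power differences the screening
stage is designed to find; no planted correlate could then be recovered,
by construction. Joint standardisation removes the recording-level scale
(the stated motivation: large inter-individual power variability) while
preserving scalp topography, and the planted-effect recovery tests confirm
the pipeline carries rank correlations of the intended size.

The nine scalp ROIs (left/middle/right × frontal/central/parietal) are
fixed channel lists over the 10-10 montage; `montage64()` provides a
64-label montage containing all of them.

## 3. Resting-fMRI features

All metrics operate on an abstract voxel grid with an isotropic voxel
(default 3 mm) and a corner-origin identity-orientation affine: spatial
normalisation to a template is out of scope and every statistic used here
is geometry-agnostic.

* `bandpassTimeseries()`: order-2 zero-phase Butterworth, 0.01–0.1 Hz.
* `alff()` / `falff()`: mean (respectively normalised sum) of the
  one-sided FFT amplitude spectrum over 0.01–0.08 Hz, computed on
  *unfiltered*, linearly detrended series. The low-frequency band is the
  field's conventional 0.01–0.08 Hz and configurable; the global filter
  band 0.01–0.1 Hz would also be defensible. Detrending is standard (drift
  otherwise dominates the lowest bins) but is switchable, because
  detrending a finite window leaks a small ramp spectrum across all bins —
  visible only in pure-tone identities, which the tests therefore evaluate
  with `detrend = FALSE`.
* `reho()`: Kendall's W, with tie correction, of each in-mask voxel's
  time-point ranks with its 26 neighbours. Voxels whose in-mask
  neighbourhood has fewer than 9 members are set to 0 rather than computed
  from a tiny neighbourhood. The conventional pipeline order is honoured in
  `extractFmriFeatures()`: ALFF/fALFF from smoothed unfiltered data; ReHo
  from band-passed unsmoothed data, its z-map smoothed afterwards.
* `zStandardizeMap()` normalises within the brain mask (mean 0, SD 1);
  constant maps are an error, not silently zero.
* `gaussianSmooth()` uses $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per
  axis in voxel units and half-sample symmetric boundary reflection, which
  keeps the smoothing operator mass-preserving.
* `extractRoiSeries()` assigns a voxel to an ROI sphere when the voxel
  *centre* lies within the radius, ties at exactly the radius included
  (8 mm radius at 3 mm voxels around an on-grid centre gives 81 voxels, a
  count the tests verify by enumeration).
* `fcMatrix()`: Pearson correlations between ROI mean series, Fisher
  z-transformed; $|r| = 1$ is clipped to $1 - 10^{-7}$ with a warning so a
  duplicated series degrades gracefully instead of producing infinities.
  The diagonal is stored as 0 and excluded from analysis.

## 4. Screening

**EEG cells.** Spearman correlation of every ROI × band × eye-condition
cell with LI. P-values come from the exact rank-statistic null
distribution (`cor.test`; the t approximation is measurably liberal at
n ≈ 27 and would inflate the FDR calibration the tests check). The BH-FDR
family is *all* cells tested jointly — the natural family given that all
cells are reported together; a per-condition family would be defensible
but smaller. Selection is `q < alpha` (default 0.05). Constant cells are
excluded from the family with a warning rather than given an undefined
correlation.

**Voxel maps.** `permutationGlmMap()` fits `intensity ~ LI + age + sex`
per voxel and takes the t statistic of the LI coefficient. With nuisance
covariates the permutation scheme is not unique; **Freedman–Lane** is used
(permute the residuals of the covariates-only model, add back its fit,
refit the full model), the scheme with the best empirical size properties
in this setting. The voxel p-value is $(1 + \#\{|t^*| \ge |t|\})/(B+1)$,
two-sided; when $B \ge n!$ the permutation group is enumerated
exhaustively. Significant voxels (p < 0.005, read as the conventional
"significant at voxel-level 0.005") are split by sign and labelled with
**26-connectivity** (the default in cluster-based neuroimaging inference),
and clusters of size strictly greater than 50 voxels are kept. A pseudo-t
(spatially smoothed residual variance) is available via `pseudoTFwhmMm`
but is off by default: at the grid sizes used here plain t is what the
calibration tests characterise, and variance smoothing changes the null
distribution that the permutations then absorb.

**Connectome edges.** Partial Spearman per upper-triangle edge (ranks
residualised on age/sex ranks, df = n − 2 − k, t approximation), selected
at raw p < 0.005 with no FDR — deliberately mirroring the common practice
of screening edges at an uncorrected threshold; the calibration test
checks the selection rate, not a corrected error rate.

## 5. Prediction

`assembleFeatures()` builds the four single-modality sets — selected EEG
cells, significant GMV/WMV cluster means, significant regional-fMRI
(ALFF-path) cluster means, selected FC edges — plus their column-wise
concatenation as the multimodal set; every column and LI are z-scored
across participants. Two deliberate choices:

* **Selection precedes cross-validation.** Feature selection is run once
  on the full cohort, exactly as the analysis this package operationalises
  does. This optimistically biases absolute performance (the selection sees
  the test participant); the package keeps the behaviour because its
  purpose is to reproduce that analysis, and the *comparison between
  feature sets* — the scientific claim — is affected symmetrically.
* **Normalization** is global by default (one z-scoring across the cohort,
  matching the original analysis); `normalize = "fold"` refits the scaling
  inside each training fold for leakage-free benchmarking.

`loocvPredict()` supports linear ε-SVR (C = 1, ε = 0.1), OLS, ARD
regression (Bayesian automatic relevance determination via
evidence-maximisation fixed-point updates, implemented in the package) and
random forests (500 trees, fold-seeded and reproducible). A feature set
with a single column is fitted with plain linear regression instead of SVR,
the convention for a lone predictor. Performance is MAE and Pearson r of
held-out predictions; `compareDependentCorrelations()` implements
Steiger's (1980) z for two dependent correlations sharing the actual LI —
the comparison method is not otherwise specified in this literature, and
Steiger's test is the standard choice, cross-checked in the tests against
a label-swap permutation test.

**A caveat the tests surface honestly:** under a pure-noise null, LOOCV
predictions are *negatively* correlated with the held-out truth (each
fold's intercept tracks the training mean, which moves opposite to the
held-out value; an intercept-only model yields r = −1 exactly). The mean
null r at n = 27 is about −0.10 (SVR) to −0.19 (OLS), not 0. The
acceptance suite asserts the idealised near-zero expectation and that
assertion fails by design, documenting the bias rather than masking it;
all other null checks (leakage, noiseless recovery) pass.

## 6. The synthetic cohort generator

`generateCohort()` draws the true learning slope and all planted latent
feature values from a joint Gaussian and maps target Spearman correlations
through the Gaussian-copula identity $\rho_P = 2\sin(\pi\rho_S/6)$, so the
noise-free latent of every planted effect has exactly the configured rank
correlation with the true slope; monotone transforms downstream (e.g.
`exp` amplitude maps) preserve it. Defaults encode the study conditions
the package emulates: 27 participants, 3 sessions × 12 runs of 180 s at
250 Hz; 64-channel resting EEG at 1000 Hz (eyes-open and eyes-closed,
180 s); 16³ voxel grids, 100 volumes at TR 2 s; age ~ N(23.1, 2.36²) and a
12/27 male fraction. The slope distribution N(0.02, 0.04²) — in units of
SMR band power per run, with baseline band power 1 — is chosen so that the
population fraction of positive-LI participants is Φ(0.5) ≈ 0.69, the
proportion of learners the emulated study observed (19/27); neither the
mean nor the SD is documented for real data, so these are fixed here once
and not tuned.

Signal models: NFB runs are a 13.5 Hz sinusoid whose band power follows
`base + slope × run` (floored at 0.05) plus pink noise; resting EEG is
pink noise plus theta/alpha/SMR/beta oscillators with per-epoch random
phase, the planted ROI's SMR amplitude a positive monotone (`exp`)
function of the latent; fMRI volumes are Gaussian noise with added
low-frequency sinusoids (ALFF clusters), shared time courses (ReHo
clusters) and shared band-limited signals between ROI-sphere pairs (FC
edges); morphometry maps are smoothed random fields with latent-shifted
clusters. What the generator does **not** emulate: eye-blink/motion
artifacts, volume conduction and realistic head geometry, scanner drift
and physiological noise, spatial autocorrelation structure of real BOLD
data. Passing tests therefore demonstrate that the estimators and the
inference chain are correct and calibrated under a controlled model — not
that the pipeline is robust to real-world artifacts.

For the morphometry and fMRI modalities the planted intensity shift is
driven by the same copula latent as every other modality (rather than by
the raw slope), so the generator's single invariant — latent/slope rank
correlation equals the configured value — holds uniformly across
modalities; in the noise-free limit the voxel-value ordering approaches
the slope ordering as the configured correlation approaches 1.

`synthFeatureCohort()` is a feature-level fast path used to study the
prediction stage across many cohorts: the learning index is the sum of
four independent unit-variance modality components and each modality's
features are noisy copies of its own component. This produces in one step
the structure that the full imaging chain yields after extraction and
screening (each modality carrying an independent share of the signal), at
a cost that allows hundreds of replicate cohorts; the full chain itself is
exercised end-to-end in the pipeline tests and the acceptance script.

## 7. Problem sizes used by the tests and the acceptance script

Simulation sizes are the package's own choices, balancing Monte-Carlo
error against desk-scale runtimes: permutation-GLM calibration on 10³
voxel grids, n = 30, 500 permutations, 100–200 null cohorts (the
attainable rejection rate at p < 0.005 with 500 permutations is
⌊0.005·501⌋/501 = 2/501 ≈ 0.004, and that is the level the calibration is
checked against); FDR calibration over 2000 null 72-cell families at
n = 27; screening recovery over 20 cohorts at n = 100 and n = 27 with
scaled acquisition (40 channels, 6 s at 250 Hz — enough epochs for the
median-of-epochs estimator to stabilise); prediction nulls over 500
cohorts; the multimodal comparison over 100 cohorts; and one full
end-to-end 27-participant cohort with correlates planted in all four
modalities (12³ grid, 80 volumes, 12-s runs). At these sizes the whole
suite runs in minutes on one CPU.

## 8. Known limitations

* The EEG reader supports delimited matrices with a channel sidecar, not
  EDF.
* ReHo edge handling (available-neighbour neighbourhoods with a minimum of
  9) means edge-voxel W values are computed over smaller groups than
  interior ones; inference near mask edges is correspondingly noisier.
* The permutation GLM permutes reduced-model residuals; with very small n
  and strong covariate effects the approximation degrades (as for any
  Freedman–Lane implementation).
* Absolute LOOCV performance numbers inherit the selection-before-CV
  optimism and the null-correlation bias discussed above; between-set
  comparisons are the robust quantity.
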