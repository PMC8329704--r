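test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- miniCohortConfig(n = 3, seed = 42L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a@groundTruth$trueSlope, b@groundTruth$trueSlope)
  expect_identical(a@nfb, b@nfb)
  expect_identical(a@eeg, b@eeg)
  expect_identical(a@fmri, b@fmri)
  expect_identical(a@gmv, b@gmv)
  expect_identical(a@covariates, b@covariates)
  c2 <- generateCohort(miniCohortConfig(n = 3, seed = 43L))
  expect_false(identical(a@groundTruth$trueSlope, c2@groundTruth$trueSlope))
})

test_that("the NFB block has nSessions x runsPerSession runs per participant", {
  cfg <- cohortConfig(nParticipants = 27, nSessions = 3, runsPerSession = 12,
                      runDurationS = 10, seed = 5L)
  coh <- generateCohort(cfg, modalities = "nfb")
  expect_length(coh@nfb, 27L)
  expect_true(all(lengths(coh@nfb) == 3L))
  expect_true(all(vapply(coh@nfb, function(s) all(lengths(s) == 12L),
                         logical(1))))
  expect_length(coh@nfb[[1]][[1]][[1]], 10 * 250)
})

test_that("copula latents reach the target Spearman correlation with the slope", {
  cfg <- cohortConfig(
    nParticipants = 2000, runDurationS = 10,
    effects = list(plantedEffect("eeg_power", list(roi = "leftCentral"),
                                 trueCorrelation = 0.6)),
    seed = 9L)
  coh <- generateCohort(cfg, modalities = character())
  gt <- groundTruth(coh)
  rho <- cor(gt$latent[, 1], gt$trueSlope, method = "spearman")
  expect_lt(abs(rho - 0.6), 0.05)
})

test_that("synthetic NFB runs carry the planted power trend", {
  cfg <- fastFeedbackConfig(prefilter = FALSE)
  set.seed(30)
  # zero slope, vanishing noise: flat medians
  meds0 <- vapply(0:3, function(r)
    median(onlineSmrPower(synthNfbRun(1.0, durationS = 12, noiseSd = 0),
                          cfg)), numeric(1))
  expect_lt(diff(range(meds0)), 1e-9)
  # positive slope, no noise: strictly increasing medians
  meds1 <- vapply(0:3, function(r)
    median(onlineSmrPower(synthNfbRun(1 + 0.3 * r, durationS = 12,
                                      noiseSd = 0), cfg)), numeric(1))
  expect_true(all(diff(meds1) > 0))
  expect_error(synthNfbRun(1, durationS = 5), "10 s")
  set.seed(7); a <- synthNfbRun(1, durationS = 10)
  set.seed(7); b <- synthNfbRun(1, durationS = 10)
  expect_identical(a, b)
})

test_that("resting EEG has the configured geometry and montage", {
  set.seed(31)
  rec <- synthRestingEeg(fs = 250, durationS = 2, nChannels = 64)
  expect_equal(dim(rec), c(64L, 500L))
  expect_true(all(unlist(scalpRoiMap()) %in% rownames(rec)))
  expect_error(synthRestingEeg(fs = 250, durationS = 2,
                               smrChannels = "NOPE"), "NOPE")
  expect_error(montage64(10), "ROI channels")
})

test_that("planted fMRI structure appears where it is planted", {
  set.seed(32)
  gs <- c(8L, 8L, 8L)
  mask <- array(TRUE, gs)
  vox <- which(array(seq_len(prod(gs)), gs) <= 40)
  vol <- synthFmri(gs, nVolumes = 60, tr = 2, mask = mask,
                   alffClusters = list(list(voxels = vox, latent = 1)),
                   noiseSd = 0.05)
  flat <- t(matrix(vol, prod(gs), 60))
  a <- alff(flat, 2)
  expect_gt(mean(a[vox]), mean(a[-vox]))
  # FC edge strength grows with the shared-signal weight
  voxA <- 1:20; voxB <- 400:420
  rFor <- function(lat) {
    set.seed(33)
    v <- synthFmri(gs, nVolumes = 80, tr = 2,
                   fcEdges = list(list(voxelsA = voxA, voxelsB = voxB,
                                       latent = lat)))
    fl <- matrix(v, prod(gs), 80)
    cor(colMeans(fl[voxA, ]), colMeans(fl[voxB, ]))
  }
  rs <- c(rFor(-2), rFor(0), rFor(2))
  expect_true(all(diff(rs) > 0))
  # no planted effects: z-standardised ALFF has mean 0, SD 1 in the mask
  v0 <- synthFmri(gs, nVolumes = 60, tr = 2)
  fl0 <- t(matrix(v0, prod(gs), 60))
  amap <- array(0, gs); amap[mask] <- alff(fl0, 2)
  z <- zStandardizeMap(amap, mask)
  expect_lt(abs(mean(z[mask])), 1e-10)
  expect_equal(sd(z[mask]), 1)
  expect_error(
    synthFmri(gs, nVolumes = 10, tr = 2,
              alffClusters = list(list(voxels = integer(0), latent = 0))))
})

test_that("morphometry clusters shift with the latent and reproduce under a seed", {
  gs <- c(8L, 8L, 8L)
  vox <- 1:30
  mapFor <- function(lat, seed) {
    set.seed(seed)
    synthMorphometry(gs, clusters = list(
      gmv = list(list(voxels = vox, latent = lat, gain = 2)),
      wmv = list()))$gmv
  }
  lo <- mapFor(-1, 40); hi <- mapFor(1, 40)
  expect_gt(mean(hi[vox] - lo[vox]), 3.9)       # 2 * gain * delta latent
  expect_lt(max(abs((hi - lo)[-vox])), 1e-12)
  expect_identical(mapFor(0.5, 41), mapFor(0.5, 41))
})

test_that("misconfigured effect geometry is reported with the effect name", {
  cfg <- miniCohortConfig(
    n = 2,
    effects = list(plantedEffect("alff", list(center = c(50, 1, 1)), 0.5)))
  expect_error(generateCohort(cfg, modalities = character()),
               "alff effect")
  cfg2 <- miniCohortConfig(
    n = 2,
    effects = list(plantedEffect("eeg_power", list(roi = "nowhere"), 0.5)))
  expect_error(generateCohort(cfg2, modalities = character()), "nowhere")
  expect_error(plantedEffect("eeg_power", list(), 1.2), "trueCorrelation")
})

test_that("ground truth is attached but never required by analysis stages", {
  cfg <- miniCohortConfig(n = 4, seed = 3L)
  coh <- generateCohort(cfg, modalities = "nfb")
  gt <- groundTruth(coh)
  expect_named(gt, c("trueSlope", "latent", "latentObserved",
                     "effectGeometry"))
  # analysis runs identically with the ground truth blanked out
  coh2 <- coh
  coh2@groundTruth <- list()
  r1 <- cohortLearningIndex(coh, fastFeedbackConfig())
  r2 <- cohortLearningIndex(coh2, fastFeedbackConfig())
  expect_identical(r1$li, r2$li)
})
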