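mkRecording <- function(nchan = 4, fs = 250, dur = 3,
                        chans = c("C5", "C3", "CP5", "CP3")) {
  m <- matrix(rnorm(nchan * fs * dur), nchan)
  rownames(m) <- chans[seq_len(nchan)]
  m
}

test_that("preprocessing epochs, high-passes and common-average re-references", {
  set.seed(10)
  x <- mkRecording(dur = 3)
  ep <- preprocessResting(x, 250, band = c(1, 100))
  expect_length(ep, 3L)
  expect_equal(ncol(ep[[1]]), 250L)
  # common average: channel sum is zero at every sample
  expect_lt(max(abs(colSums(ep[[2]]))), 1e-9)
  # a large DC offset is removed by the 1 Hz high-pass
  epDc <- preprocessResting(x + 50, 250, band = c(1, 100), reref = FALSE)
  expect_lt(max(abs(rowMeans(epDc[[2]]))), 0.5)
  expect_error(preprocessResting(x[, 1:100, drop = FALSE], 250), "1 s")
  expect_error(preprocessResting(x, 150), "200")
})

test_that("Welch PSD matches the mean-of-modified-periodograms oracle", {
  set.seed(11)
  x <- rnorm(700)
  W <- welchPsd(x, fs = 100, nfft = 256)
  O <- oracleWelch(x, fs = 100, nfft = 256)
  expect_equal(W$freq, O$freq, tolerance = 1e-12)
  expect_equal(W$psd, O$psd, tolerance = 1e-10)
})

test_that("Welch PSD integrates to the variance and peaks at the tone frequency", {
  set.seed(12)
  x <- rnorm(60000, sd = 2)
  W <- welchPsd(x, fs = 1000, nfft = 1000)
  df <- 1000 / 1000
  expect_equal(sum(W$psd) * df, var(x), tolerance = 0.05)
  t <- seq_len(5000) / 1000
  Ws <- welchPsd(sin(2 * pi * 10 * t), fs = 1000, nfft = 1000)
  expect_equal(Ws$freq[which.max(Ws$psd)], 10)
  expect_error(welchPsd(rnorm(500), 1000, nfft = 1000), "minimum segment")
})

test_that("relative band power is a fraction with the expected identities", {
  t <- seq_len(4000) / 1000
  W <- welchPsd(sin(2 * pi * 10 * t) + 0.01 * rnorm(4000), fs = 1000,
                nfft = 1000)
  expect_equal(relativeBandPower(W, c(1, 100), c(1, 100)), 1.0)
  expect_gt(relativeBandPower(W, c(8, 12), c(1, 100)), 0.95)
  expect_lt(relativeBandPower(W, c(20, 30), c(1, 100)), 0.01)
  expect_error(relativeBandPower(W, c(10, 10)), "zero")
})

test_that("relative powers are invariant to global rescaling of the signal", {
  set.seed(13)
  x <- mkRecording(dur = 4)
  ep1 <- preprocessResting(x, 250)
  ep2 <- preprocessResting(5 * x, 250)
  t1 <- roiBandTable(ep1, 250, roiMap = list(lc = c("C5", "C3")),
                     bands = bandScheme())
  t2 <- roiBandTable(ep2, 250, roiMap = list(lc = c("C5", "C3")),
                     bands = bandScheme())
  expect_equal(t1, t2, tolerance = 1e-8)
})

test_that("ROI aggregation averages channels and is permutation-invariant", {
  set.seed(14)
  x <- mkRecording(dur = 4)
  ep <- preprocessResting(x, 250)
  tAll <- roiBandTable(ep, 250,
                       roiMap = list(a = c("C5", "C3", "CP5", "CP3")),
                       bands = bandScheme())
  tPerm <- roiBandTable(ep, 250,
                        roiMap = list(a = c("CP3", "C5", "CP5", "C3")),
                        bands = bandScheme())
  expect_equal(tAll, tPerm)
  # an ROI of identical channels equals the single-channel value
  y <- mkRecording(nchan = 1, chans = "C3", dur = 4)
  dup <- rbind(y, y); rownames(dup) <- c("C3", "C5")
  epd <- lapply(seq_len(4), function(e)
    dup[, ((e - 1) * 250 + 1):(e * 250), drop = FALSE])
  tDup <- roiBandTable(epd, 250, roiMap = list(both = c("C3", "C5"),
                                               one = "C3"),
                       bands = bandScheme())
  expect_equal(tDup["both", ], tDup["one", ])
  expect_error(roiBandTable(ep, 250, roiMap = list(a = c("C3", "Oz"))),
               "Oz")
})

test_that("missing ROI channels and flat recordings are reported", {
  flat <- matrix(1, 2, 500, dimnames = list(c("C3", "C5"), NULL))
  ep <- lapply(1:2, function(e) flat[, ((e - 1) * 250 + 1):(e * 250)])
  suppressWarnings(
    expect_warning(roiBandTable(ep, 250, roiMap = list(a = "C3"),
                                bands = bandScheme(smr = c(12, 15))),
                   "zero dispersion"))
  tb <- suppressWarnings(roiBandTable(ep, 250, roiMap = list(a = "C3"),
                                      bands = bandScheme()))
  expect_true(all(tb == 0))
})

test_that("boosting an oscillator raises that band's relative power", {
  set.seed(15)
  t <- seq_len(4 * 250) / 250
  base <- function(aAlpha) {
    m <- rbind(pinkNoiseTest(1000) + aAlpha * sin(2 * pi * 10 * t),
               pinkNoiseTest(1000))
    rownames(m) <- c("C3", "C5")
    m
  }
  pinkNoiseTest <- function(n) rnorm(n)  # white is fine for monotonicity
  ep1 <- preprocessResting(base(1), 250, reref = FALSE)
  ep2 <- preprocessResting(base(2), 250, reref = FALSE)
  relAlpha <- function(ep) {
    W <- welchPsd(ep[[2]]["C3", ], 250, nfft = 250)
    relativeBandPower(W, c(8, 12), c(1, 100))
  }
  expect_gt(relAlpha(ep2), relAlpha(ep1))
})

test_that("planted SMR latents order the extracted left-central SMR value", {
  # two participants differing only in the planted latent, no feature noise
  tableFor <- function(latent, seed) {
    set.seed(seed)
    rec <- synthRestingEeg(fs = 250, durationS = 4, nChannels = 40,
                           smrLatent = latent,
                           smrChannels = scalpRoiMap()$leftCentral)
    ep <- preprocessResting(rec, 250)
    roiBandTable(ep, 250, bands = bandScheme())["leftCentral", "smr"]
  }
  lo <- tableFor(-1.5, 21)
  hi <- tableFor(1.5, 21)
  expect_gt(hi, lo)
})
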