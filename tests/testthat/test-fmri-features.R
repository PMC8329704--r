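test_that("the 0.01-0.1 Hz band-pass passes slow and rejects fast oscillations", {
  tr <- 2
  tt <- seq_len(300) * tr
  slow <- sin(2 * pi * 0.05 * tt)
  fast <- sin(2 * pi * 0.2 * tt)
  expect_gt(sd(bandpassTimeseries(slow, tr)) / sd(slow), 0.9)
  expect_lt(sd(bandpassTimeseries(fast, tr)) / sd(fast), 0.1)
  expect_lt(max(abs(bandpassTimeseries(rep(4, 300), tr))), 1e-6)
})

test_that("ALFF and fALFF match the explicit-DFT oracle", {
  set.seed(20)
  tr <- 2
  for (rep in 1:5) {
    x <- rnorm(60) + 0.5 * sin(2 * pi * 0.03 * seq_len(60) * tr)
    o <- oracleAlff(x, tr)
    expect_equal(alff(x, tr), o$alff, tolerance = 1e-10)
    expect_equal(falff(x, tr), o$falff, tolerance = 1e-10)
  }
})

test_that("ALFF is linear in amplitude; fALFF is scale-invariant and bounded", {
  tr <- 2
  tt <- seq_len(100) * tr
  s <- sin(2 * pi * 0.03 * tt)
  expect_equal(alff(2 * s, tr) / alff(s, tr), 2, tolerance = 1e-9)
  set.seed(21)
  x <- rnorm(100)
  expect_gt(alff(x + s, tr), alff(x, tr))
  expect_equal(falff(7 * (x + s), tr), falff(x + s, tr), tolerance = 1e-12)
  expect_gt(falff(s, tr, detrend = FALSE), 0.99)       # pure in-band tone
  expect_lt(falff(sin(2 * pi * 0.2 * tt), tr, detrend = FALSE), 0.05)
  expect_true(falff(x, tr) >= 0 && falff(x, tr) <= 1)
})

test_that("ReHo is 1 for identical series and matches the textbook W formula", {
  set.seed(22)
  # identical series in a full 3x3x3 neighbourhood
  a <- array(rep(rnorm(50), each = 27), c(3, 3, 3, 50))
  m <- array(TRUE, c(3, 3, 3))
  expect_equal(reho(a, m)[2, 2, 2], 1)
  # hand-computed 3-series toy: ranks (1,2,3,4), (2,1,4,3), (1,3,2,4)
  # rank sums (4,6,9,11), S = 29, denom = 9*60/12 = 45, W = 29/45
  s1 <- c(10, 20, 30, 40); s2 <- c(5, 1, 50, 20); s3 <- c(2, 9, 5, 11)
  expect_equal(oracleKendallW(list(s1, s2, s3)), 29 / 45)
  line <- array(0, c(3, 1, 1, 4))
  line[1, 1, 1, ] <- s1; line[2, 1, 1, ] <- s2; line[3, 1, 1, ] <- s3
  W <- reho(line, array(TRUE, c(3, 1, 1)), minNeighbors = 3L)
  expect_equal(W[2, 1, 1], 29 / 45, tolerance = 1e-12)
  # random toys against the oracle, including ties
  for (rep in 1:5) {
    sl <- list(sample(1:6, 6, TRUE), rnorm(6), sample(1:3, 6, TRUE))
    line <- array(0, c(3, 1, 1, 6))
    for (i in 1:3) line[i, 1, 1, ] <- sl[[i]]
    expect_equal(reho(line, array(TRUE, c(3, 1, 1)), minNeighbors = 3L)[2, 1, 1],
                 oracleKendallW(sl), tolerance = 1e-12)
  }
})

test_that("ReHo of independent noise is near its small null level", {
  set.seed(23)
  a <- array(rnorm(27 * 100), c(3, 3, 3, 100))
  W <- reho(a, array(TRUE, c(3, 3, 3)))[2, 2, 2]
  expect_lt(W, 0.15)
  expect_error(reho(array(0, c(3, 3, 3, 1)), array(TRUE, c(3, 3, 3))),
               "2 time points")
})

test_that("ReHo is invariant to per-voxel linear intensity rescaling", {
  set.seed(24)
  a <- array(rnorm(27 * 30), c(3, 3, 3, 30))
  b <- a * 3.7 + 11
  m <- array(TRUE, c(3, 3, 3))
  expect_equal(reho(a, m), reho(b, m), tolerance = 1e-12)
})

test_that("map z-standardisation yields mean 0 / SD 1 and is affine-invariant", {
  set.seed(25)
  m <- array(c(rep(TRUE, 20), rep(FALSE, 7)), c(3, 3, 3))
  x <- array(rnorm(27), c(3, 3, 3))
  z <- zStandardizeMap(x, m)
  expect_lt(abs(mean(z[m])), 1e-10)
  expect_equal(sd(z[m]), 1)
  expect_true(all(z[!m] == 0))
  expect_equal(zStandardizeMap(3 * x + 5, m), z, tolerance = 1e-10)
  expect_error(zStandardizeMap(array(2, c(3, 3, 3)), m), "zero SD")
})

test_that("Gaussian smoothing has the closed-form sigma and preserves totals", {
  d <- array(0, c(16, 16, 16)); d[8, 8, 8] <- 1
  sm <- gaussianSmooth(d, 6, 3)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(sigma, 0.8493218, tolerance = 1e-6)
  rad <- ceiling(4 * sigma)
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2)); k <- k / sum(k)
  peak <- max(k)^3
  expect_equal(sm[8, 8, 8], peak, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # kernel separability: off-centre value is the product of 1D kernel weights
  expect_equal(sm[9, 8, 8], k[rad + 2] * max(k)^2, tolerance = 1e-12)
})

test_that("ROI sphere extraction counts voxels by world distance", {
  vol <- array(rnorm(16^3 * 5), c(16, 16, 16, 5))
  # 8 mm radius at 3 mm voxels around an on-grid centre: 81 voxels
  rt <- data.frame(name = "a", x = 21, y = 21, z = 21, radius = 8)
  grid <- arrayInd(seq_len(16^3), c(16, 16, 16))
  sel <- rowSums(sweep((grid - 1) * 3, 2, c(21, 21, 21))^2) <= 64
  expect_equal(sum(sel), 81L)
  flat <- matrix(vol, 16^3, 5)
  expect_equal(drop(extractRoiSeries(vol, rt)),
               colMeans(flat[sel, ]), tolerance = 1e-12)
  # a sphere covering exactly one voxel returns that voxel's series
  rt1 <- data.frame(name = "b", x = 21, y = 21, z = 21, radius = 1)
  expect_equal(drop(extractRoiSeries(vol, rt1)), vol[8, 8, 8, ])
  # a uniform volume gives identical constant series for every ROI
  u <- array(3, c(16, 16, 16, 4))
  rs <- extractRoiSeries(u, rbind(rt, rt1))
  expect_true(all(rs == 3))
  # empty sphere errors with the ROI name
  rtFar <- data.frame(name = "far", x = 21, y = 21, z = 21, radius = 8)
  mask <- array(FALSE, c(16, 16, 16))
  expect_error(extractRoiSeries(vol, rtFar, mask = mask), "far")
})

test_that("connectivity is Fisher z with symmetric structure and safe clipping", {
  set.seed(26)
  x <- matrix(rnorm(600), 3, 200, dimnames = list(c("a", "b", "c"), NULL))
  z <- fcMatrix(x)
  expect_true(isSymmetric(z))
  expect_equal(diag(z), c(a = 0, b = 0, c = 0))
  expect_equal(z["a", "b"], atanh(cor(x["a", ], x["b", ])))
  # ROI permutation permutes the matrix
  p <- c(3, 1, 2)
  expect_equal(fcMatrix(x[p, ]), z[p, p])
  # identical series clip with a warning instead of returning Inf
  xx <- rbind(x, d = x["a", ])
  expect_warning(z2 <- fcMatrix(xx), "clipped")
  expect_true(is.finite(z2["a", "d"]))
  expect_equal(z2["a", "d"], atanh(1 - 1e-7))
  bad <- x; bad["b", ] <- 5
  expect_error(fcMatrix(bad), "b")
})

test_that("r = 0.5 maps to z = 0.5493 and r = 0 to z = 0", {
  expect_equal(atanh(0.5), 0.5493061, tolerance = 1e-7)
  n <- 200
  a <- sin(seq_len(n)); b <- cos(seq_len(n))  # near-orthogonal
  z <- fcMatrix(rbind(a = a, b = b))
  expect_lt(abs(z["a", "b"]), 0.02)
})
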