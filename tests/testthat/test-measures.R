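test_that("PLI hits its defining limits", {
  set.seed(1)
  ph <- runif(2000, -pi, pi)
  expect_identical(pli(ph, ph), 0)                 # zero lag -> 0
  expect_identical(pli(ph + pi / 2, ph), 1)        # constant non-zero lag -> 1
  expect_identical(pli(rep(c(pi / 4, -pi / 4), 100), rep(0, 200)), 0)
  expect_error(pli(numeric(0), numeric(0)), "empty")
})

test_that("PLI is invariant to common phase offsets and argument order", {
  set.seed(2)
  px <- runif(500, -pi, pi)
  py <- runif(500, -pi, pi)
  for (off in c(0.3, -1.2, 2)) {
    expect_equal(pli(px + off, py + off), pli(px, py), tolerance = 1e-12)
  }
  expect_equal(pli(py, px), pli(px, py), tolerance = 1e-12)
})

test_that("vectorized estimators agree with naive loop oracles", {
  set.seed(3)
  px <- runif(100, -pi, pi); py <- runif(100, -pi, pi)
  expect_equal(pli(px, py), pliLoop(px, py), tolerance = 1e-12)
  x <- rnorm(100)
  for (m in 2:4)
    expect_equal(permutationEntropy(x, m = m), peLoop(x, m, 1),
                 tolerance = 1e-12)
  expect_equal(suppressWarnings(permutationEntropy(x, m = 3, tau = 3)),
               peLoop(x, 3, 3), tolerance = 1e-12)
})

test_that("ordinal patterns follow the occurrence-order tie rule", {
  expect_equal(length(unique(ordinalPatterns(1:50, m = 3)$symbols)), 1L)
  expect_equal(length(unique(ordinalPatterns(rep(1, 50), m = 3)$symbols)), 1L)
  # constant and ascending series map to the same (ascending) pattern
  expect_equal(unique(ordinalPatterns(rep(1, 50), m = 3)$symbols),
               unique(ordinalPatterns(1:50, m = 3)$symbols))
  # [4,2,7] and any series ranking middle<first<last share one symbol
  expect_equal(ordinalPatterns(c(4, 2, 7), m = 3)$symbols,
               ordinalPatterns(c(10, -5, 11), m = 3)$symbols)
  op <- ordinalPatterns(rnorm(100), m = 4, tau = 2)
  expect_length(op$symbols, 100 - 3 * 2)
  expect_true(all(op$symbols >= 0 & op$symbols < 24))
  expect_error(ordinalPatterns(1:10, m = 1), "m must be >= 2")
  expect_error(ordinalPatterns(1:3, m = 3, tau = 2), "too short")
})

test_that("permutation entropy matches hand-computable distributions", {
  expect_equal(permutationEntropy(1:1000), 0)
  # alternating saw: exactly 2 of the 6 patterns, equally often
  saw <- rep(c(0, 1), 300)
  expect_equal(permutationEntropy(saw, m = 3), log(2) / log(6),
               tolerance = 1e-9)
  set.seed(4)
  expect_gte(permutationEntropy(runif(1e5), m = 3), 0.99)
  expect_warning(permutationEntropy(rnorm(6), m = 3), "under-sampled")
})

test_that("PE and JPE are invariant to strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(400); y <- rnorm(400)
  f <- function(v) exp(2 * v) + 1          # strictly increasing
  expect_equal(permutationEntropy(f(x)), permutationEntropy(x),
               tolerance = 1e-12)
  expect_equal(jpeInv(f(x), f(y)), jpeInv(x, y), tolerance = 1e-12)
})

test_that("inverted joint permutation entropy hits its analytic anchors", {
  set.seed(6)
  x <- rnorm(1e5)
  expect_equal(jpeInv(x, x), 0.5, tolerance = 0.01)     # diagonal support
  expect_lt(jpeInv(x, rnorm(1e5)), 0.02)                # independence -> 0
  r <- seq_len(500)
  expect_equal(jpeInv(r, r), 1)                         # one joint pattern
  expect_warning(jpeInv(rnorm(20), rnorm(20)), "under-sampled")
})

test_that("AECc behaves under the null and detects co-modulation", {
  fs <- 256
  # independent channels: raw r ~ 0, normalized ~ 0.5
  raws <- sapply(1:20, function(s) {
    set.seed(s)
    b <- canonicalBands()$alpha
    x <- as.numeric(bandpass(matrix(rnorm(fs * 8), 1), b, fs = fs))
    y <- as.numeric(bandpass(matrix(rnorm(fs * 8), 1), b, fs = fs))
    aecc(x, y)$raw
  })
  expect_lt(abs(mean(raws)), 0.1)
  expect_equal(mean(raws) / 2 + 0.5, mean(raws / 2 + 0.5), tolerance = 1e-12)

  # identical signals: residual vanishes -> undefined
  set.seed(30)
  x <- as.numeric(bandpass(matrix(rnorm(fs * 8), 1), canonicalBands()$alpha,
                           fs = fs))
  expect_true(is.na(aecc(x, x)$value))

  # shared signal + noise: corrected raw correlation stays near 0
  rShared <- sapply(1:20, function(s) {
    set.seed(100 + s)
    b <- canonicalBands()$alpha
    x <- as.numeric(bandpass(matrix(rnorm(fs * 8), 1), b, fs = fs))
    n <- as.numeric(bandpass(matrix(rnorm(fs * 8), 1), b, fs = fs))
    aecc(x, x + 0.05 * n)$raw
  })
  expect_lt(abs(mean(rShared)), 0.15)

  # co-modulated envelopes with independent carriers: raw r well above null
  rCo <- sapply(1:10, function(s) {
    p <- generateCoupledPair(0.9, "amplitude", fs * 8, fs, seed = s)
    aecc(p$x, p$y)$raw
  })
  expect_gt(mean(rCo), mean(raws) + 0.2)
  expect_gt(mean(rCo) / 2 + 0.5, 0.5)
})

test_that("connectivity matrices are symmetric, zero-diagonal, permutation-consistent", {
  fs <- 128
  set.seed(8)
  x <- matrix(rnorm(3 * fs * 12), nrow = 3,
              dimnames = list(c("Fz", "Cz", "Pz"), NULL))
  rec <- alphaRecording(x, fs, nEpochs = 3, epochLenS = 2)
  for (meas in c("PLI", "AECc", "JPE_INV")) {
    cm <- connectivityMatrix(rec, meas)
    w <- connectivityWeights(cm)
    expect_equal(w, t(w))
    expect_equal(unname(diag(w)), rep(0, 3))
    expect_length(unique(w[upper.tri(w)]), 3L)
    expect_true(all(w[upper.tri(w)] >= 0 & w[upper.tri(w)] <= 1))
  }

  # permuting channels permutes rows/columns consistently
  perm <- c(3, 1, 2)
  recP <- rec
  recP@data <- rec@data[perm, , , drop = FALSE]
  recP@channelLabels <- rec@channelLabels[perm]
  w1 <- connectivityWeights(connectivityMatrix(rec, "PLI"))
  w2 <- connectivityWeights(connectivityMatrix(recP, "PLI"))
  expect_equal(w2, w1[perm, perm], tolerance = 1e-12)
})

test_that("epoch averaging of identical epochs equals the single-epoch value", {
  fs <- 128
  set.seed(9)
  oneEpoch <- matrix(rnorm(2 * fs * 2), nrow = 2)
  x <- cbind(oneEpoch, oneEpoch, oneEpoch)
  rec <- alphaRecording(x, fs, nEpochs = 3, epochLenS = 2)
  rec1 <- alphaRecording(x[, 1:(2 * fs), drop = FALSE], fs, nEpochs = 1,
                         epochLenS = 2)
  # filtering the tripled record is not identical at the seams; rebuild epochs
  rec@data <- array(rep(rec1@data, 3), dim = c(2, 2 * fs, 3))
  v3 <- wholeBrainMean(connectivityMatrix(rec, "PLI"))
  v1 <- wholeBrainMean(connectivityMatrix(rec1, "PLI"))
  expect_equal(v3, v1, tolerance = 1e-12)
})

test_that("whole-brain mean is the upper-triangle average", {
  w <- matrix(0.3, 4, 4); diag(w) <- 0
  dimnames(w) <- list(letters[1:4], letters[1:4])
  expect_equal(wholeBrainMean(w), 0.3)
  w2 <- randomWeightMatrix(2, seed = 1)
  expect_equal(wholeBrainMean(w2), w2[1, 2])
  w3 <- randomWeightMatrix(6, seed = 2)
  perm <- sample(6)
  expect_equal(wholeBrainMean(w3[perm, perm]), wholeBrainMean(w3))
})

test_that("per-channel entropy returns the whole-head mean of channel PEs", {
  fs <- 128
  set.seed(10)
  rec <- segmentEpochs(matrix(rnorm(3 * fs * 8), 3), fs = fs, epochLenS = 2,
                       nEpochs = 4)
  ce <- channelEntropy(rec)
  expect_length(ce$perChannel, 3L)
  expect_equal(ce$mean, mean(ce$perChannel))
  expect_true(all(ce$perChannel > 0.9))   # near-iid noise is high-entropy
})
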