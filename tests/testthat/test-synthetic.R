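test_that("coupled-pair generator is deterministic and validates inputs", {
  p1 <- generateCoupledPair(0.5, "phase", 1024, 128, seed = 5)
  p2 <- generateCoupledPair(0.5, "phase", 1024, 128, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1,
                         generateCoupledPair(0.5, "phase", 1024, 128,
                                             seed = 6)))
  expect_error(generateCoupledPair(0.5, "phase", 1024, 128,
                                   band = bandDefinition("x", 40, 70)),
               "fs/2")
  expect_error(bandDefinition("bad", 8, 8), "degenerate")
  expect_warning(generateCoupledPair(0.5, "phase", 1024, 128, phaseLag = 0),
                 "blind to zero-lag")
  expect_error(generateCoupledPair(1.2, "phase", 1024, 128))
})

test_that("phase mode spans the PLI range from chance level to 1", {
  fs <- 128
  trim <- 200:3896
  pliOf <- function(pair) {
    pli(analyticSignal(pair$x)$phase[trim], analyticSignal(pair$y)$phase[trim])
  }
  # coupling 1, quarter-cycle lag, noise-free: perfect locking
  expect_equal(pliOf(generateCoupledPair(1, "phase", 4096, fs, seed = 1)), 1)

  # coupling 0: mean PLI matches the estimator's own chance level on
  # independent narrowband noise (Monte-Carlo oracle), well below coupled
  zero <- sapply(1:40, function(s)
    pliOf(generateCoupledPair(0, "phase", 4096, fs, seed = s)))
  chance <- sapply(1:40, function(s) {
    set.seed(90000 + s)
    b <- canonicalBands()$alpha
    x <- as.numeric(bandpass(matrix(rnorm(4096), 1), b, fs = fs))
    y <- as.numeric(bandpass(matrix(rnorm(4096), 1), b, fs = fs))
    pli(analyticSignal(x)$phase[trim], analyticSignal(y)$phase[trim])
  })
  expect_lt(abs(mean(zero) - mean(chance)), 0.05)
  strong <- sapply(1:10, function(s)
    pliOf(generateCoupledPair(0.8, "phase", 4096, fs, seed = s)))
  expect_gt(mean(strong), mean(zero) + 0.3)
})

test_that("each mode responds monotonically to its coupling grid", {
  fs <- 128
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  trim <- 200:3896
  means <- function(f) sapply(grid, function(cp)
    mean(sapply(1:50, function(s) f(cp, s))))

  mPhase <- means(function(cp, s) {
    p <- generateCoupledPair(cp, "phase", 4096, fs, seed = s)
    pli(analyticSignal(p$x)$phase[trim], analyticSignal(p$y)$phase[trim])
  })
  expect_gt(cor(grid, mPhase, method = "spearman"), 0.9)

  mAmp <- means(function(cp, s) {
    p <- generateCoupledPair(cp, "amplitude", 2048, fs, seed = s)
    aecc(p$x, p$y)$raw
  })
  expect_gt(cor(grid, mAmp, method = "spearman"), 0.9)
  # explicit pairwise check at matched seeds for the envelope example
  e05 <- mean(sapply(1:25, function(s) {
    p <- generateCoupledPair(0.5, "amplitude", 2048, fs, seed = s)
    aecc(p$x, p$y)$raw
  }))
  e01 <- mean(sapply(1:25, function(s) {
    p <- generateCoupledPair(0.1, "amplitude", 2048, fs, seed = s)
    aecc(p$x, p$y)$raw
  }))
  expect_gt(e05, e01)

  mOrd <- means(function(cp, s) {
    p <- generateCoupledPair(cp, "ordinal", 2048, fs, seed = s)
    jpeInv(p$x, p$y)
  })
  expect_gt(cor(grid, mOrd, method = "spearman"), 0.9)
})

test_that("generated signals are finite, demeaned after filtering, correctly shaped", {
  cfg <- cohortConfig(nSubjects = 2, nChannels = 3, fs = 64, nEpochs = 3,
                      epochLenS = 2, seed = 4)
  co <- generateCohort(cfg)
  x <- co$recordings[["s01"]][["session1"]]
  expect_equal(dim(x), c(3, 3 * 2 * 64))
  expect_true(all(is.finite(x)))
  rec <- segmentEpochs(x, fs = 64, epochLenS = 2, nEpochs = 3)
  expect_equal(dim(rec@data), c(3, 128, 3))
  expect_equal(max(abs(apply(rec@data, c(1, 3), mean))), 0, tolerance = 1e-12)
})

test_that("cohort generation is deterministic and honours variance switches", {
  cfg <- cohortConfig(nSubjects = 3, nChannels = 3, fs = 64, nEpochs = 2,
                      epochLenS = 2, sigmaState = 0, sigmaNoise = 0,
                      seed = 11)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$recordings, b$recordings)

  # no within-subject variance: the three conditions are bit-identical
  for (s in names(a$recordings)) {
    expect_identical(a$recordings[[s]]$session1, a$recordings[[s]]$session2)
    expect_identical(a$recordings[[s]]$session1, a$recordings[[s]]$semirest)
  }
  expect_false(identical(a$recordings$s01$session1,
                         a$recordings$s02$session1))

  withNoise <- generateCohort(
    cohortConfig(nSubjects = 3, nChannels = 3, fs = 64, nEpochs = 2,
                 epochLenS = 2, sigmaState = 0.02, sigmaNoise = 0.02,
                 seed = 11))
  expect_false(identical(withNoise$recordings$s01$session1,
                         withNoise$recordings$s01$session2))
})

test_that("theoretical ICCs follow the variance-component formulas", {
  cfg <- cohortConfig(nSubjects = 2, nChannels = 2, fs = 64, nEpochs = 1,
                      epochLenS = 1, sigmaSubject = 1, sigmaState = 0,
                      sigmaNoise = 1, couplingBase = 0.5)
  # sigmaSubject = 1 clips many couplings; only the formulas matter here
  gt <- suppressWarnings(generateCohort(cfg))$groundTruth
  expect_equal(gt$iccTheoreticalAgreement, 0.5)     # 1 / (1 + 1)
  expect_equal(gt$iccTheoreticalConsistency, 0.5)

  y <- generateScalarTable(50, 2, sigmaSubject = 2, sigmaSession = 1,
                           sigmaNoise = 1, seed = 3)
  expect_equal(attr(y, "iccTheoretical"), 4 / 5)
  expect_error(generateScalarTable(1, 2), "nSubjects >= 2")
  expect_error(generateScalarTable(10, 2, sigmaNoise = -1), ">= 0")
  expect_error(generateCohort(cohortConfig(nSubjects = 1)), "nSubjects >= 2")
})

test_that("heavy clipping of couplings is flagged", {
  cfg <- cohortConfig(nSubjects = 4, nChannels = 2, fs = 64, nEpochs = 1,
                      epochLenS = 1, sigmaSubject = 0.8, couplingBase = 0.9,
                      seed = 2)
  expect_warning(generateCohort(cfg), "clipped")
})

test_that("scalar tables reach ICC 1 when within-subject variance is zero", {
  y <- generateScalarTable(20, 2, sigmaSubject = 1, sigmaSession = 0,
                           sigmaNoise = 0, seed = 9)
  expect_equal(icc2way(y)$icc, 1)
})
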