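#' Configuration for a synthetic EEG cohort
#'
#' Describes a subjects x {session1, session2, semirest} study with known
#' variance components. Each recording's channel-pair coupling is
#' \code{clip01(couplingBase + c_s + d_r + e_sr)} with the subject trait
#' \code{c_s ~ N(0, sigmaSubject)}, a condition-level state shift
#' \code{d_r ~ N(0, sigmaState)} and recording-level measurement noise
#' \code{e_sr ~ N(0, sigmaNoise)}; Gaussian components match the two-way
#' ANOVA model the ICC assumes. The default signal geometry mirrors the
#' sensor-EEG study layout: 64 channels at 2048 Hz, 15 epochs of 4 s.
#'
#' @param nSubjects number of subjects (>= 2; the ICC is undefined below 3).
#' @param nChannels channels (default 64).
#' @param fs sampling rate in Hz (default 2048).
#' @param nEpochs epochs per recording (default 15).
#' @param epochLenS epoch length in seconds (default 4).
#' @param bands list of [BandDefinition-class] (default [canonicalBands()]).
#' @param sigmaSubject between-subject SD of the latent coupling trait.
#' @param sigmaState SD of the condition-level coupling shift.
#' @param sigmaNoise SD of the within-recording coupling noise.
#' @param couplingBase mean coupling strength in [0, 1].
#' @param seed integer RNG seed; one global seed expands to per-subject /
#'   per-condition child seeds via [childSeed()], so identical seeds give
#'   bit-identical cohorts and subsets are reproducible.
#' @return a validated list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(nSubjects, nChannels = 64L, fs = 2048, nEpochs = 15L,
                         epochLenS = 4, bands = canonicalBands(),
                         sigmaSubject = 0.10, sigmaState = 0.04,
                         sigmaNoise = 0.04, couplingBase = 0.4, seed = 1L) {
  stopifnot(nSubjects >= 2, nChannels >= 2, fs > 0, nEpochs >= 1,
            epochLenS > 0)
  if (min(sigmaSubject, sigmaState, sigmaNoise) < 0)
    stop("standard deviations must be >= 0")
  if (couplingBase < 0 || couplingBase > 1)
    stop("couplingBase must lie in [0, 1]")
  cfg <- list(nSubjects = as.integer(nSubjects),
              nChannels = as.integer(nChannels), fs = fs,
              nEpochs = as.integer(nEpochs), epochLenS = epochLenS,
              bands = bands, sigmaSubject = sigmaSubject,
              sigmaState = sigmaState, sigmaNoise = sigmaNoise,
              couplingBase = couplingBase, seed = as.integer(seed))
  class(cfg) <- "cohortConfig"
  cfg
}

## white noise filtered to a band, unit variance
narrowbandNoise <- function(n, fs, band, flt = NULL) {
  if (is.null(flt)) flt <- firBandpassFilter(fs, band, maxLen = n)
  v <- applyZeroPhase(stats::rnorm(n), flt)
  v / stats::sd(v)
}

## constant phase rotation through the analytic representation (all-pass)
rotatePhase <- function(x, phaseLag) Re(analyticVec(x) * exp(-1i * phaseLag))

#' Generate a pair of signals with controlled coupling
#'
#' Produces two band-limited signals whose coupling is tunable in [0, 1],
#' one mode per estimator family:
#' \describe{
#'   \item{phase}{a shared narrowband source is mixed into both channels
#'     (\code{sqrt(coupling) * common + sqrt(1 - coupling) * private}), the
#'     second channel's copy rotated by a constant non-zero phase lag, so
#'     the phase lag index responds monotonically to \code{coupling}.}
#'   \item{amplitude}{two independent narrowband carriers are multiplied by
#'     log-normal envelopes whose underlying slow modulators share a common
#'     component with weight \code{coupling}, driving the envelope
#'     correlation.}
#'   \item{ordinal}{a shared broadband source injects common ordinal-pattern
#'     structure into both channels with weight \code{coupling}.}
#' }
#'
#' @param coupling coupling strength in [0, 1].
#' @param mode \code{"phase"}, \code{"amplitude"} or \code{"ordinal"}.
#' @param nSamples number of samples per signal.
#' @param fs sampling rate in Hz.
#' @param band a [BandDefinition-class] within (0, fs/2).
#' @param phaseLag phase lag in radians, in (-pi, pi]; a zero lag with
#'   \code{mode = "phase"} triggers a warning because the phase lag index is
#'   blind to zero-lag coupling by construction.
#' @param seed RNG seed.
#' @return list with numeric vectors \code{x} and \code{y}.
#' @export
generateCoupledPair <- function(coupling, mode = c("phase", "amplitude",
                                                   "ordinal"),
                                nSamples, fs, band = canonicalBands()$alpha,
                                phaseLag = pi / 2, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(coupling >= 0, coupling <= 1, nSamples > 8)
  if (phaseLag <= -pi || phaseLag > pi)
    stop("phaseLag must lie in (-pi, pi]")
  validObject(band)
  if (band@high >= fs / 2) stop("band must lie within (0, fs/2)")
  if (mode == "phase" && phaseLag == 0)
    warning("phaseLag = 0: the phase lag index is blind to zero-lag coupling")
  a <- sqrt(coupling); b <- sqrt(1 - coupling)
  withSeed(seed, {
    flt <- firBandpassFilter(fs, band, maxLen = nSamples)
    if (mode == "phase") {
      common <- narrowbandNoise(nSamples, fs, band, flt)
      p1 <- narrowbandNoise(nSamples, fs, band, flt)
      p2 <- narrowbandNoise(nSamples, fs, band, flt)
      x <- a * common + b * p1
      y <- a * rotatePhase(common, phaseLag) + b * p2
    } else if (mode == "amplitude") {
      c1 <- narrowbandNoise(nSamples, fs, band, flt)
      c2 <- narrowbandNoise(nSamples, fs, band, flt)
      mS <- slowModulator(nSamples, fs)
      m1 <- a * mS + b * slowModulator(nSamples, fs)
      m2 <- a * mS + b * slowModulator(nSamples, fs)
      x <- c1 * exp(0.5 * m1)
      y <- c2 * exp(0.5 * m2)
    } else {
      common <- stats::rnorm(nSamples)
      x <- a * common + b * stats::rnorm(nSamples)
      y <- a * common + b * stats::rnorm(nSamples)
    }
    list(x = x, y = y)
  })
}

## smooth unit-variance modulator (moving-average of white noise, ~fs/4 win)
slowModulator <- function(n, fs) {
  win <- max(8L, as.integer(fs / 4))
  v <- stats::filter(stats::rnorm(n + win), rep(1 / win, win), sides = 1)
  v <- as.numeric(v[(win + 1L):(n + win)])
  (v - mean(v)) / stats::sd(v)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic cohort with known ground truth
#'
#' For every subject and condition (\code{session1}, \code{session2},
#' \code{semirest}) a continuous multichannel recording is generated in
#' which every channel mixes a phase-shifted copy of a subject-specific
#' common source (weight \code{sqrt(coupling)}) with private noise. Signal
#' innovations are seeded per subject only, so two conditions with equal
#' coupling produce bit-identical recordings: with
#' \code{sigmaState = sigmaNoise = 0} all downstream measures are exactly
#' equal across conditions and every theoretical ICC is 1.
#'
#' Couplings falling outside [0, 1] are clipped; the clipping rate is
#' reported and a warning is raised above 1 percent because clipping biases
#' the nominal variance components.
#'
#' @param config a [cohortConfig()].
#' @return list of class \code{"syntheticCohort"}: \code{recordings} (nested
#'   list \code{[[subject]][[condition]]} of channels x samples matrices),
#'   \code{fs}, \code{channelLabels}, \code{conditions}, \code{config}, and
#'   \code{groundTruth} with the drawn components (\code{traits},
#'   \code{stateShifts}, \code{coupling} matrix), the clipping rate, and the
#'   theoretical ICCs \code{iccTheoreticalConsistency} =
#'   sigmaSubject^2 / (sigmaSubject^2 + sigmaNoise^2) (the condition shift is
#'   a column effect that the consistency ICC removes) and
#'   \code{iccTheoreticalAgreement} =
#'   sigmaSubject^2 / (sigmaSubject^2 + sigmaState^2 + sigmaNoise^2).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  if (config$nSubjects < 2L) stop("need at least 2 subjects")
  conditions <- c("session1", "session2", "semirest")
  nS <- config$nSubjects
  nCh <- config$nChannels
  nSamples <- as.integer(round(config$nEpochs * config$epochLenS * config$fs))
  labels <- sprintf("ch%02d", seq_len(nCh))
  phaseOffsets <- seq(0.3, 2.6, length.out = nCh)

  traits <- vapply(seq_len(nS), function(s)
    withSeed(childSeed(config$seed, "trait", s),
             stats::rnorm(1, 0, config$sigmaSubject)), numeric(1))
  stateShifts <- vapply(seq_along(conditions), function(r)
    withSeed(childSeed(config$seed, "state", r),
             stats::rnorm(1, 0, config$sigmaState)), numeric(1))
  names(stateShifts) <- conditions

  coupling <- matrix(NA_real_, nS, length(conditions),
                     dimnames = list(sprintf("s%02d", seq_len(nS)),
                                     conditions))
  rawCoupling <- coupling
  recordings <- vector("list", nS)
  names(recordings) <- rownames(coupling)
  wideband <- bandDefinition("wide", 0.5, min(20, config$fs / 2 * 0.9))
  for (s in seq_len(nS)) {
    base <- withSeed(childSeed(config$seed, "signal", s), {
      flt <- firBandpassFilter(config$fs, wideband, maxLen = nSamples)
      common <- narrowbandNoise(nSamples, config$fs, wideband, flt)
      priv <- matrix(NA_real_, nCh, nSamples)
      for (ch in seq_len(nCh))
        priv[ch, ] <- narrowbandNoise(nSamples, config$fs, wideband, flt)
      shifted <- matrix(NA_real_, nCh, nSamples)
      for (ch in seq_len(nCh))
        shifted[ch, ] <- rotatePhase(common, phaseOffsets[ch])
      list(shifted = shifted, priv = priv)
    })
    recordings[[s]] <- vector("list", length(conditions))
    names(recordings[[s]]) <- conditions
    for (r in seq_along(conditions)) {
      eps <- if (config$sigmaNoise > 0)
        withSeed(childSeed(config$seed, "noise", s, r),
                 stats::rnorm(1, 0, config$sigmaNoise)) else 0
      cRaw <- config$couplingBase + traits[s] + stateShifts[r] + eps
      cClip <- clip01(cRaw)
      rawCoupling[s, r] <- cRaw
      coupling[s, r] <- cClip
      x <- sqrt(cClip) * base$shifted + sqrt(1 - cClip) * base$priv
      rownames(x) <- labels
      recordings[[s]][[r]] <- x
    }
  }
  clipRate <- mean(rawCoupling < 0 | rawCoupling > 1)
  if (clipRate > 0.01)
    warning(sprintf(
      "%.1f%% of couplings clipped to [0,1]; ground-truth variance components are biased",
      100 * clipRate))
  v <- config$sigmaSubject^2
  gt <- list(
    traits = traits, stateShifts = stateShifts, coupling = coupling,
    clipRate = clipRate,
    iccTheoreticalConsistency = if (v + config$sigmaNoise^2 > 0)
      v / (v + config$sigmaNoise^2) else 1,
    iccTheoreticalAgreement = if (v + config$sigmaState^2 +
                                  config$sigmaNoise^2 > 0)
      v / (v + config$sigmaState^2 + config$sigmaNoise^2) else 1)
  structure(list(recordings = recordings, fs = config$fs,
                 channelLabels = labels, conditions = conditions,
                 config = config, groundTruth = gt),
            class = "syntheticCohort")
}

#' Generate a scalar measurement table with known variance components
#'
#' Direct stress-test input for the reliability layer, bypassing signal
#' simulation: \code{y_sr = mu + b_s + g_r + e_sr} with independent Gaussian
#' components (subject effect SD \code{sigmaSubject}, session effect SD
#' \code{sigmaSession}, residual SD \code{sigmaNoise}). The consistency ICC
#' of this model is \code{sigmaSubject^2 / (sigmaSubject^2 + sigmaNoise^2)}
#' (the session effect is a column effect), attached as attribute
#' \code{"iccTheoretical"}.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param nSessions number of sessions (>= 2).
#' @param sigmaSubject,sigmaSession,sigmaNoise component SDs (>= 0).
#' @param mu grand mean.
#' @param seed RNG seed.
#' @return numeric matrix subjects x sessions with attribute
#'   \code{"iccTheoretical"}.
#' @export
generateScalarTable <- function(nSubjects, nSessions = 2L, sigmaSubject = 1,
                                sigmaSession = 0, sigmaNoise = 1, mu = 0,
                                seed = 1L) {
  stopifnot(nSubjects >= 2, nSessions >= 2)
  if (min(sigmaSubject, sigmaSession, sigmaNoise) < 0)
    stop("standard deviations must be >= 0")
  y <- withSeed(seed, {
    b <- stats::rnorm(nSubjects, 0, sigmaSubject)
    g <- stats::rnorm(nSessions, 0, sigmaSession)
    e <- matrix(stats::rnorm(nSubjects * nSessions, 0, sigmaNoise),
                nSubjects, nSessions)
    mu + outer(b, g, "+") + e
  })
  dimnames(y) <- list(sprintf("s%03d", seq_len(nSubjects)),
                      sprintf("session%d", seq_len(nSessions)))
  tot <- sigmaSubject^2 + sigmaNoise^2
  attr(y, "iccTheoretical") <- if (tot > 0) sigmaSubject^2 / tot else 1
  y
}
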