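#' Phase lag index
#'
#' Quantifies the consistency of non-zero instantaneous phase differences
#' between two signals: \code{|mean(sign(dphi))|} with \code{dphi} wrapped to
#' (-pi, pi]. Exact zero differences contribute 0 to the mean, so perfect
#' zero-lag (volume-conduction-like) coupling maps to 0, and a constant
#' non-zero lag maps to 1.
#'
#' @param phaseX,phaseY equal-length instantaneous phase series in radians.
#' @return value in [0, 1].
#' @examples
#' ph <- runif(1000, -pi, pi)
#' pli(ph, ph)            # identical signals -> 0
#' pli(ph + pi / 2, ph)   # constant quarter-cycle lag -> 1
#' @export
pli <- function(phaseX, phaseY) {
  if (length(phaseX) == 0L) stop("empty phase series")
  if (length(phaseX) != length(phaseY))
    stop("phase series must have equal length")
  d <- wrapPhase(phaseX - phaseY)
  abs(mean(sign(d)))
}

## wrap angles to (-pi, pi]
wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Corrected amplitude envelope correlation
#'
#' Leakage-corrected envelope coupling for a pair of band-filtered signals:
#' one signal is orthogonalized with respect to the other by removing its
#' least-squares projection in the time domain, the amplitude envelopes of
#' the reference and the residual are correlated (Pearson), the computation
#' is repeated with the roles swapped, and the two correlations are averaged.
#' The signed average \code{r} is mapped to [0, 1] as \code{(r + 1) / 2};
#' both are returned. A fraction of samples at each end is excluded from the
#' correlation to suppress analytic-signal edge effects.
#'
#' @param x,y equal-length band-filtered signals.
#' @param edgeTrimFrac fraction of samples trimmed from each end of the
#'   envelopes before correlating (default 0.1).
#' @return list with \code{value} (normalized, in [0, 1]) and \code{raw} (the
#'   signed averaged correlation). Both are \code{NA} when an envelope has
#'   zero variance (e.g. \code{y} exactly proportional to \code{x}, so the
#'   residual vanishes).
#' @export
aecc <- function(x, y, edgeTrimFrac = 0.1) {
  if (length(x) != length(y)) stop("signals must have equal length")
  x <- x - mean(x)
  y <- y - mean(y)
  n <- length(x)
  keep <- envKeepIndex(n, edgeTrimFrac)
  zx <- analyticVec(x)
  zy <- analyticVec(y)
  r1 <- orthEnvCor(x, zx, y, zy, keep)
  r2 <- orthEnvCor(y, zy, x, zx, keep)
  r <- (r1 + r2) / 2
  list(value = (r + 1) / 2, raw = r)
}

## correlation of env(ref) with env(target - proj onto ref); the analytic
## transform is linear, so the residual's analytic signal is formed from the
## precomputed transforms.
orthEnvCor <- function(ref, zRef, tgt, zTgt, keep) {
  den <- sum(ref * ref)
  if (den == 0) return(NA_real_)
  beta <- sum(ref * tgt) / den
  envRef <- Mod(zRef)[keep]
  envRes <- Mod(zTgt - beta * zRef)[keep]
  if (stats::sd(envRef) == 0 || stats::sd(envRes) == 0) return(NA_real_)
  stats::cor(envRef, envRes)
}

envKeepIndex <- function(n, edgeTrimFrac) {
  trim <- floor(n * edgeTrimFrac)
  if (2 * trim >= n - 2) trim <- 0L
  (trim + 1L):(n - trim)
}

#' Ordinal patterns of a time series
#'
#' Maps each delay-embedded window of \code{m} points to the permutation that
#' ranks its values (Bandt-Pompe symbolization). Ties are broken by order of
#' occurrence: the earlier sample receives the lower rank, so a constant
#' window maps to the ascending pattern. The symbol alphabet has size
#' \code{factorial(m)}.
#'
#' @param x numeric series with \code{length(x) >= (m - 1) * tau + 1}.
#' @param m embedding dimension, 2..5.
#' @param tau embedding delay in samples.
#' @return list: \code{symbols} integer vector in \code{0:(factorial(m)-1)}
#'   of length \code{length(x) - (m - 1) * tau}, plus \code{m}, \code{tau}.
#' @examples
#' ordinalPatterns(c(4, 2, 7), m = 3)$symbols
#' @export
ordinalPatterns <- function(x, m = 3L, tau = 1L) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 2L) stop("embedding dimension m must be >= 2")
  if (m > 5L) stop("embedding dimension m capped at 5 (alphabet size m!)")
  if (tau < 1L) stop("tau must be >= 1")
  nW <- length(x) - (m - 1L) * tau
  if (nW < 1L)
    stop(sprintf("series of length %d too short for m=%d, tau=%d",
                 length(x), m, tau))
  idx <- outer(seq_len(nW), (0:(m - 1L)) * tau, "+")
  W <- matrix(x[idx], nrow = nW)
  ## rank of column i = 1 + #{j: w_j < w_i} + #{j < i: w_j == w_i}
  ranks <- matrix(1L, nrow = nW, ncol = m)
  for (i in seq_len(m))
    for (j in seq_len(m)) {
      if (j == i) next
      lt <- W[, j] < W[, i]
      if (j < i) lt <- lt | (W[, j] == W[, i])
      ranks[, i] <- ranks[, i] + lt
    }
  ## Lehmer-style encoding of the rank vector -> 0..m!-1
  sym <- integer(nW)
  for (i in seq_len(m - 1L)) {
    higherLater <- integer(nW)
    for (j in (i + 1L):m) higherLater <- higherLater + (ranks[, j] < ranks[, i])
    sym <- sym * (m - i + 1L) + higherLater
  }
  list(symbols = sym, m = m, tau = tau)
}

#' Permutation entropy
#'
#' Normalized Shannon entropy of the empirical ordinal-pattern distribution
#' of a single series; 0 for a fully predictable (monotone) signal, 1 in the
#' limit of i.i.d. noise. A local complexity measure computed per channel.
#'
#' @inheritParams ordinalPatterns
#' @return value in [0, 1].
#' @examples
#' permutationEntropy(seq_len(100))        # monotone ramp -> 0
#' @export
permutationEntropy <- function(x, m = 3L, tau = 1L) {
  op <- ordinalPatterns(x, m, tau)
  k <- factorial(op$m)
  if (length(op$symbols) < k)
    warning("fewer windows than alphabet size; pattern distribution is ",
            "under-sampled")
  p <- tabulate(op$symbols + 1L, nbins = k)
  p <- p[p > 0] / length(op$symbols)
  -sum(p * log(p)) / log(k)
}

#' Inverted joint permutation entropy
#'
#' Normalized Shannon entropy of the joint distribution of simultaneous
#' ordinal-pattern pairs from two channels, normalized by
#' \code{log(factorial(m)^2)} so that independent i.i.d. noise attains 1, and
#' inverted (\code{1 - JPE}) so that larger values mean stronger coupling.
#'
#' @param x,y equal-length series.
#' @inheritParams ordinalPatterns
#' @return \code{JPE_INV} in [0, 1].
#' @examples
#' r <- seq_len(200)
#' jpeInv(r, r)   # two monotone ramps: one joint pattern -> 1
#' @export
jpeInv <- function(x, y, m = 3L, tau = 1L) {
  if (length(x) != length(y)) stop("series must have equal length")
  sx <- ordinalPatterns(x, m, tau)
  sy <- ordinalPatterns(y, m, tau)
  k <- factorial(sx$m)
  if (length(sx$symbols) < k * k)
    warning("fewer windows than joint alphabet size; distribution is ",
            "under-sampled")
  joint <- sx$symbols * k + sy$symbols
  p <- tabulate(joint + 1L, nbins = k * k)
  p <- p[p > 0] / length(joint)
  jpe <- -sum(p * log(p)) / log(k^2)
  1 - jpe
}

#' Epoch-averaged connectivity matrix
#'
#' Computes one pairwise measure for every channel pair of every epoch and
#' averages across epochs. PLI and AECc require band-filtered input; pattern
#' symbols for the joint permutation entropy are computed once per channel
#' and epoch. Pairs whose AECc is undefined in an epoch (zero-variance
#' envelope) are averaged over the remaining epochs and counted in
#' \code{aux$droppedEpochs}.
#'
#' @param recording an [EpochedRecording-class].
#' @param measure \code{"PLI"}, \code{"AECc"} or \code{"JPE_INV"}.
#' @param m,tau ordinal-pattern parameters for \code{"JPE_INV"}.
#' @param edgeTrimFrac fraction of samples trimmed from each epoch end for
#'   phase/envelope statistics (default 0.1).
#' @return a [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(recording, measure = c("PLI", "AECc", "JPE_INV"),
                               m = 3L, tau = 1L, edgeTrimFrac = 0.1) {
  stopifnot(is(recording, "EpochedRecording"))
  measure <- match.arg(measure)
  if (measure %in% c("PLI", "AECc") && is.null(recording@band))
    stop(measure, " requires band-filtered input; call bandpass() first")
  nCh <- dim(recording@data)[1L]
  nSm <- dim(recording@data)[2L]
  nEp <- dim(recording@data)[3L]
  labels <- recording@channelLabels
  acc <- matrix(0, nCh, nCh)
  cnt <- matrix(0L, nCh, nCh)
  rawAcc <- if (measure == "AECc") matrix(0, nCh, nCh) else NULL
  keep <- envKeepIndex(nSm, edgeTrimFrac)

  for (e in seq_len(nEp)) {
    ep <- recording@data[, , e, drop = TRUE]
    ep <- rbind(ep)                      # keep matrix shape at nCh = 1
    ep <- ep - rowMeans(ep)
    if (measure == "PLI") {
      ph <- t(apply(ep, 1L, function(v) Arg(analyticVec(v))))[, keep,
                                                              drop = FALSE]
      for (i in seq_len(nCh - 1L))
        for (j in (i + 1L):nCh) {
          v <- pli(ph[i, ], ph[j, ])
          acc[i, j] <- acc[i, j] + v
          cnt[i, j] <- cnt[i, j] + 1L
        }
    } else if (measure == "AECc") {
      Z <- t(apply(ep, 1L, analyticVec))
      for (i in seq_len(nCh - 1L))
        for (j in (i + 1L):nCh) {
          r1 <- orthEnvCor(ep[i, ], Z[i, ], ep[j, ], Z[j, ], keep)
          r2 <- orthEnvCor(ep[j, ], Z[j, ], ep[i, ], Z[i, ], keep)
          r <- (r1 + r2) / 2
          if (is.na(r)) next
          acc[i, j] <- acc[i, j] + (r + 1) / 2
          rawAcc[i, j] <- rawAcc[i, j] + r
          cnt[i, j] <- cnt[i, j] + 1L
        }
    } else {
      syms <- lapply(seq_len(nCh),
                     function(ch) ordinalPatterns(ep[ch, ], m, tau)$symbols)
      for (i in seq_len(nCh - 1L))
        for (j in (i + 1L):nCh) {
          v <- jointEntropyInv(syms[[i]], syms[[j]], m)
          acc[i, j] <- acc[i, j] + v
          cnt[i, j] <- cnt[i, j] + 1L
        }
      }
  }
  dropped <- nEp - cnt
  dropped[lower.tri(dropped, diag = TRUE)] <- 0L
  if (any(dropped > 0L))
    message(sprintf("%d pair-epoch value(s) undefined and excluded from %s",
                    sum(dropped), measure))
  symmetrize <- function(num) {
    v <- num / pmax(cnt, 1L)
    v[lower.tri(v, diag = TRUE)] <- 0
    v[cnt == 0L & upper.tri(cnt)] <- NA_real_   # pair missing in all epochs
    v <- v + t(v)
    diag(v) <- 0
    dimnames(v) <- list(labels, labels)
    v
  }
  w <- symmetrize(acc)
  aux <- list(droppedEpochs = dropped)
  if (measure == "AECc") aux$raw <- symmetrize(rawAcc)
  new("ConnectivityMatrix", weights = w, measure = measure,
      band = recording@band, nEpochs = as.integer(nEp), aux = aux)
}

## JPE_INV from precomputed per-channel symbol streams
jointEntropyInv <- function(sx, sy, m) {
  k <- factorial(m)
  p <- tabulate(sx * k + sy + 1L, nbins = k * k)
  p <- p[p > 0] / length(sx)
  1 - (-sum(p * log(p)) / log(k^2))
}

#' Per-channel permutation entropy of a recording
#'
#' Computes PE per channel and epoch, averages across epochs, and returns the
#' per-channel vector together with the whole-head mean (the scalar summary
#' used in the reliability analysis).
#'
#' @param recording an [EpochedRecording-class].
#' @inheritParams ordinalPatterns
#' @return list with \code{perChannel} (named numeric) and \code{mean}.
#' @export
channelEntropy <- function(recording, m = 3L, tau = 1L) {
  stopifnot(is(recording, "EpochedRecording"))
  nCh <- dim(recording@data)[1L]
  nEp <- dim(recording@data)[3L]
  vals <- matrix(NA_real_, nCh, nEp)
  for (e in seq_len(nEp))
    for (ch in seq_len(nCh))
      vals[ch, e] <- permutationEntropy(recording@data[ch, , e], m, tau)
  perChannel <- rowMeans(vals)
  names(perChannel) <- recording@channelLabels
  list(perChannel = perChannel, mean = mean(perChannel))
}

#' @describeIn wholeBrainMean mean of the upper triangle of the weight matrix.
#' @export
setMethod("wholeBrainMean", "ConnectivityMatrix", function(x) {
  w <- x@weights
  mean(w[upper.tri(w)], na.rm = TRUE)
})

#' @describeIn wholeBrainMean method for a plain symmetric matrix.
#' @export
setMethod("wholeBrainMean", "matrix", function(x) {
  mean(x[upper.tri(x)], na.rm = TRUE)
})
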