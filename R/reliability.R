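#' Two-way mixed-effects intraclass correlation coefficient
#'
#' Single-rater two-way mixed-effects ICC from the two-way ANOVA
#' decomposition of a subjects x sessions table. The default is the
#' consistency form (Shrout-Fleiss ICC(3,1)),
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k - 1) MS_E),}
#' which ignores a systematic session offset; the absolute-agreement form
#' (McGraw-Wong ICC(A,1) under a mixed model) additionally charges the
#' session variance:
#' \deqn{ICC_A = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)).}
#' The 95\% confidence interval is F-based: exact for consistency, and the
#' Satterthwaite approximation for agreement.
#'
#' @param values numeric matrix, subjects x sessions (k >= 2), or a
#'   data.frame with columns \code{subject}, \code{session}, \code{value}.
#'   Subjects with any missing session are dropped pairwise (counted in the
#'   result).
#' @param type \code{"consistency"} (default) or \code{"agreement"}.
#' @param conf confidence level (default 0.95).
#' @param truncateNegative clamp negative point estimates to 0 (default
#'   \code{FALSE}; negative estimates are reported as computed).
#' @return list: \code{icc}, \code{ci_low}, \code{ci_high}, \code{type},
#'   \code{n} (complete subjects), \code{k}, \code{n_dropped},
#'   \code{degenerate} (\code{TRUE} when the within-subject mean square is
#'   zero so the interval collapses), and the mean squares \code{ms}.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(40), 20, 2) + rnorm(20)
#' icc2way(y)
#' @export
icc2way <- function(values, type = c("consistency", "agreement"),
                    conf = 0.95, truncateNegative = FALSE) {
  type <- match.arg(type)
  y <- asSessionMatrix(values)
  nDropped <- attr(y, "nDropped")
  n <- nrow(y); k <- ncol(y)
  if (n < 3L) stop("need at least 3 complete subjects for the ICC")
  if (!all(is.finite(y))) stop("non-finite values")
  grand <- mean(y)
  rm_ <- rowMeans(y); cm <- colMeans(y)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sst <- sum((y - grand)^2)
  sse <- sst - (n - 1) * msr - (k - 1) * msc
  ## guard tiny negative rounding
  sse <- max(sse, 0)
  dfe <- (n - 1) * (k - 1)
  mse <- sse / dfe
  alpha <- 1 - conf
  degenerate <- mse == 0
  if (degenerate) {
    ## zero within-subject (residual) variance: the point estimate is exact
    ## but the F machinery collapses, so the interval degenerates.
    icc <- if (type == "consistency") 1 else {
      den <- msr + (k - 1) * mse + k / n * (msc - mse)
      if (den == 0) 1 else (msr - mse) / den   # all-identical table -> 1
    }
    res <- list(icc = icc, ci_low = icc, ci_high = icc)
  } else if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    Fobs <- msr / mse
    FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, dfe)
    FU <- Fobs * stats::qf(1 - alpha / 2, dfe, n - 1)
    res <- list(icc = icc,
                ci_low = (FL - 1) / (FL + k - 1),
                ci_high = (FU - 1) / (FU + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    ## McGraw & Wong (1996) interval for single-measure absolute agreement
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / dfe)
    FstarL <- stats::qf(1 - alpha / 2, n - 1, v)
    FstarU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - FstarL * mse) /
      (FstarL * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (FstarU * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * FstarU * msr)
    res <- list(icc = icc, ci_low = lo, ci_high = hi)
  }
  if (truncateNegative) {
    res$icc <- max(res$icc, 0)
    res$ci_low <- max(res$ci_low, 0)
    res$ci_high <- max(res$ci_high, 0)
  }
  res$ci_low <- min(res$ci_low, res$icc)
  res$ci_high <- max(res$ci_high, res$icc)
  c(res, list(type = type, n = n, k = k, n_dropped = nDropped,
              degenerate = degenerate,
              ms = c(msr = msr, msc = msc, mse = mse)))
}

asSessionMatrix <- function(values) {
  if (is.matrix(values)) {
    keep <- stats::complete.cases(values)
    y <- values[keep, , drop = FALSE]
    attr(y, "nDropped") <- sum(!keep)
    return(y)
  }
  stopifnot(is.data.frame(values),
            all(c("subject", "session", "value") %in% names(values)))
  wide <- stats::reshape(
    values[, c("subject", "session", "value")], idvar = "subject",
    timevar = "session", direction = "wide")
  y <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(y) <- wide$subject
  keep <- stats::complete.cases(y)
  out <- y[keep, , drop = FALSE]
  attr(out, "nDropped") <- sum(!keep)
  out
}

#' Non-parametric bootstrap confidence interval for the ICC
#'
#' Resamples subjects (rows, kept paired across sessions) with replacement,
#' recomputes the ICC on each resample, and returns the 2.5/97.5 percentile
#' interval (1000 resamples by default). Resamples containing fewer than 3
#' distinct subjects are redrawn and counted.
#'
#' @inheritParams icc2way
#' @param nResamples number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling.
#' @return list: \code{ci_low}, \code{ci_high}, \code{n_resamples},
#'   \code{n_redrawn}, and the vector of resampled estimates
#'   \code{estimates}.
#' @export
iccBootstrapCI <- function(values, type = c("consistency", "agreement"),
                           nResamples = 1000L, seed = 1L, conf = 0.95) {
  type <- match.arg(type)
  y <- asSessionMatrix(values)
  n <- nrow(y)
  if (n < 3L) stop("need at least 3 complete subjects")
  est <- numeric(nResamples)
  nRedrawn <- 0L
  withSeed(seed, {
    for (b in seq_len(nResamples)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= 3L) break
        nRedrawn <- nRedrawn + 1L
      }
      est[b] <- suppressWarnings(icc2way(y[idx, , drop = FALSE],
                                         type = type)$icc)
    }
  })
  if (nRedrawn > 0L)
    message(nRedrawn, " degenerate resample(s) redrawn")
  qs <- stats::quantile(est, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  list(ci_low = qs[1L], ci_high = qs[2L], n_resamples = nResamples,
       n_redrawn = nRedrawn, estimates = est)
}

#' Koo & Li reliability category
#'
#' Maps an ICC to the conventional reliability bands: below 0.50 poor, 0.50
#' to 0.75 moderate, 0.76 to 0.90 good, above 0.90 excellent. Values are
#' rounded to two decimals first, mirroring the printed banding (so the gap
#' between 0.75 and 0.76 cannot swallow a value). The category can be based
#' on the point estimate (default) or on the lower confidence bound.
#'
#' @param icc ICC point estimate(s) in [-1, 1] (negative estimates are
#'   categorized poor), or the list returned by [icc2way()].
#' @param basis \code{"point"} or \code{"ci_low"}; only used when \code{icc}
#'   is an [icc2way()] result.
#' @return factor with levels poor < moderate < good < excellent.
#' @examples
#' categorizeICC(c(0.49, 0.60, 0.91))
#' @export
categorizeICC <- function(icc, basis = c("point", "ci_low")) {
  basis <- match.arg(basis)
  if (is.list(icc))
    icc <- if (basis == "ci_low") icc$ci_low else icc$icc
  stopifnot(all(icc >= -1 & icc <= 1))
  x <- round(icc, 2)
  lab <- ifelse(x < 0.50, "poor",
         ifelse(x <= 0.75, "moderate",
         ifelse(x <= 0.90, "good", "excellent")))
  factor(lab, levels = c("poor", "moderate", "good", "excellent"),
         ordered = TRUE)
}

#' Four-way state/temporal biomarker classification
#'
#' Combines the reliability category of the temporal comparison (repeated
#' resting-state sessions weeks apart) with that of the state comparison
#' (resting-state vs semi-resting-state on the same day). "High" reliability
#' means any category at or above the configurable cut (default
#' \code{"moderate"}).
#'
#' @param temporal,state reliability categories (as returned by
#'   [categorizeICC()], or their labels).
#' @param highAt lowest category counted as "high" (default
#'   \code{"moderate"}).
#' @return one of \code{"possible biomarker"}, \code{"possible biomarker,
#'   sensitive to resting-state instructions"}, \code{"possible
#'   cross-sectional marker, sensitive to time-variable factors"},
#'   \code{"poor reliability"}.
#' @examples
#' classifyBiomarker("good", "good")
#' classifyBiomarker("good", "poor")
#' @export
classifyBiomarker <- function(temporal, state, highAt = "moderate") {
  lv <- c("poor", "moderate", "good", "excellent")
  rank <- function(x) match(as.character(x), lv)
  if (anyNA(rank(temporal)) || anyNA(rank(state)) || anyNA(rank(highAt)))
    stop("categories must be poor/moderate/good/excellent")
  tHigh <- rank(temporal) >= rank(highAt)
  sHigh <- rank(state) >= rank(highAt)
  ifelse(tHigh & sHigh, "possible biomarker",
  ifelse(tHigh & !sHigh,
         "possible biomarker, sensitive to resting-state instructions",
  ifelse(!tHigh & sHigh,
         "possible cross-sectional marker, sensitive to time-variable factors",
         "poor reliability")))
}
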