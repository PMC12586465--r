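#' Construct a frequency band
#'
#' @param name band label.
#' @param low,high passband edges in Hz, \code{0 < low < high}.
#' @return a [BandDefinition-class].
#' @examples
#' bandDefinition("alpha", 8, 13)
#' @export
bandDefinition <- function(name, low, high) {
  new("BandDefinition", name = as.character(name), low = as.numeric(low),
      high = as.numeric(high))
}

#' Canonical sensor-EEG frequency bands
#'
#' delta 0.5--4, theta 4--8, alpha 8--13, beta 13--20 Hz. Content above
#' 20 Hz is excluded to reduce muscle-activity contamination.
#'
#' @return named list of [BandDefinition-class] objects.
#' @export
canonicalBands <- function() {
  list(delta = bandDefinition("delta", 0.5, 4),
       theta = bandDefinition("theta", 4, 8),
       alpha = bandDefinition("alpha", 8, 13),
       beta  = bandDefinition("beta", 13, 20))
}

## Windowed-sinc (Hamming) FIR band-pass, applied forward-backward for zero
## phase. Order follows the Hamming transition-width rule n ~ 3.3 fs / tbw,
## with the transition band chosen as min(max(low/4, 2 Hz), low) below the
## passband (mirrored above), and is capped so filtfilt remains valid for
## short inputs.
firBandpassFilter <- function(fs, band, maxLen = Inf) {
  tbwLow <- min(max(band@low / 4, 2), band@low)
  tbwHigh <- min(max(band@high / 4, 2), max(fs / 2 - band@high, 1e-6))
  tbw <- min(tbwLow, tbwHigh)
  n <- ceiling(3.3 * fs / tbw)
  n <- n + n %% 2L                       # even order -> odd-length kernel
  cap <- floor((maxLen - 1) / 3)
  if (n > cap) {
    n <- max(2L, cap - cap %% 2L)
    message(sprintf(
      "filter order capped at %d for signal length %d; transition bands widen",
      n, maxLen))
  }
  w <- c(band@low, band@high) / (fs / 2)
  signal::fir1(n, w, type = "pass")
}

applyZeroPhase <- function(x, flt) as.numeric(signal::filtfilt(flt, x))

#' Zero-phase FIR band-pass filtering
#'
#' Filters either a continuous multichannel matrix or an
#' [EpochedRecording-class] into a single frequency band with a windowed-sinc
#' (Hamming) FIR filter applied forward and backward, so the passband incurs
#' no phase distortion (phase distortion would corrupt the phase lag index).
#' When continuous data are available, filter first and segment afterwards so
#' that edge transients fall outside the epochs; filtering an already epoched
#' recording filters each epoch independently and is flagged with a message.
#'
#' @param x continuous numeric matrix (channels x samples) or an
#'   [EpochedRecording-class] (broadband).
#' @param band a [BandDefinition-class]; its upper edge must be below the
#'   Nyquist frequency.
#' @param fs sampling rate in Hz (taken from the recording when \code{x} is an
#'   [EpochedRecording-class]).
#' @return object of the same shape as \code{x}, band-filtered, with the band
#'   recorded.
#' @examples
#' fs <- 256
#' x <- matrix(sin(2 * pi * 10 * seq_len(fs * 4) / fs), nrow = 1)
#' y <- bandpass(x, canonicalBands()$alpha, fs = fs)
#' @export
bandpass <- function(x, band, fs = NULL) {
  stopifnot(is(band, "BandDefinition"))
  if (is(x, "EpochedRecording")) {
    if (!is.null(x@band))
      stop("recording is already band-filtered (", x@band@name,
           "); bandpass expects broadband input")
    if (band@high >= x@fs / 2)
      stop("band upper edge ", band@high, " Hz is at or above Nyquist (",
           x@fs / 2, " Hz)")
    message("filtering per epoch; prefer filtering continuous data before ",
            "segmentation when available")
    flt <- firBandpassFilter(x@fs, band, maxLen = dim(x@data)[2L])
    out <- x@data
    for (e in seq_len(dim(out)[3L]))
      for (ch in seq_len(dim(out)[1L]))
        out[ch, , e] <- applyZeroPhase(x@data[ch, , e], flt)
    ans <- x
    ans@data <- out
    ans@band <- band
    validObject(ans)
    return(ans)
  }
  if (is.null(fs)) stop("'fs' is required for matrix input")
  if (band@high >= fs / 2)
    stop("band upper edge ", band@high, " Hz is at or above Nyquist (",
         fs / 2, " Hz)")
  x <- rbind(x)
  flt <- firBandpassFilter(fs, band, maxLen = ncol(x))
  t(apply(x, 1L, applyZeroPhase, flt = flt))
}

#' Segment a continuous recording into fixed-length epochs
#'
#' Takes consecutive non-overlapping epochs from the start of the record
#' (synthetic data carry no artifacts, so "first N clean" reduces to the
#' first N) and removes each channel's per-epoch mean.
#'
#' @param x numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param epochLenS epoch length in seconds (default 4).
#' @param nEpochs number of epochs (default 15).
#' @param channelLabels optional channel names; defaults to rownames or
#'   \code{ch01, ch02, ...}.
#' @param band [BandDefinition-class] the data were filtered in, or
#'   \code{NULL} for broadband.
#' @param subjectId,condition labels stored on the recording.
#' @return an [EpochedRecording-class].
#' @examples
#' x <- matrix(rnorm(2 * 2048 * 60), nrow = 2)   # 60 s at 2048 Hz
#' rec <- segmentEpochs(x, fs = 2048)            # 15 epochs x 8192 samples
#' @export
segmentEpochs <- function(x, fs, epochLenS = 4, nEpochs = 15,
                          channelLabels = NULL, band = NULL,
                          subjectId = "s01", condition = "session1") {
  x <- rbind(x)
  nPer <- round(epochLenS * fs)
  maxEpochs <- ncol(x) %/% nPer
  if (nEpochs > maxEpochs)
    stop(sprintf(
      "record of %d samples supports at most %d epoch(s) of %g s at %g Hz (%d requested)",
      ncol(x), maxEpochs, epochLenS, fs, nEpochs))
  if (is.null(channelLabels))
    channelLabels <- rownames(x) %||% sprintf("ch%02d", seq_len(nrow(x)))
  a <- array(NA_real_, dim = c(nrow(x), nPer, nEpochs))
  for (e in seq_len(nEpochs)) {
    seg <- x[, ((e - 1L) * nPer + 1L):(e * nPer), drop = FALSE]
    a[, , e] <- seg - rowMeans(seg)
  }
  new("EpochedRecording", data = a, fs = fs, channelLabels = channelLabels,
      band = band, subjectId = subjectId, condition = condition)
}

#' Analytic signal: instantaneous phase and amplitude envelope
#'
#' Computes the discrete analytic signal of each channel of each epoch by the
#' frequency-domain construction (positive frequencies doubled, negative
#' zeroed), after removing the epoch mean. Returns instantaneous phase in
#' (-pi, pi] and the non-negative amplitude envelope. Phase is only
#' physically interpretable for narrowband input; broadband input triggers a
#' warning.
#'
#' @param x an [EpochedRecording-class], or a numeric vector (single signal).
#' @return for a recording, a list with arrays \code{phase} and
#'   \code{envelope} of the same dimensions as the data; for a vector, a list
#'   with vectors \code{phase} and \code{envelope}.
#' @examples
#' s <- sin(2 * pi * 10 * seq_len(1024) / 256)
#' a <- analyticSignal(s)
#' range(a$envelope[100:900])   # ~1
#' @export
analyticSignal <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    z <- analyticVec(x - mean(x))
    return(list(phase = Arg(z), envelope = Mod(z)))
  }
  stopifnot(is(x, "EpochedRecording"))
  if (is.null(x@band))
    warning("broadband input: instantaneous phase is ill-defined; ",
            "band-pass filter first")
  ph <- env <- array(NA_real_, dim = dim(x@data))
  for (e in seq_len(dim(x@data)[3L]))
    for (ch in seq_len(dim(x@data)[1L])) {
      v <- x@data[ch, , e]
      z <- analyticVec(v - mean(v))
      ph[ch, , e] <- Arg(z)
      env[ch, , e] <- Mod(z)
    }
  list(phase = ph, envelope = env)
}

## FFT-based analytic signal (Marple construction).
analyticVec <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Join consecutive short epochs into longer segments
#'
#' The amplitude-envelope correlation can alternatively be computed on
#' one-minute concatenated segments instead of separate 4-s epochs; this
#' groups runs of consecutive epochs into segments of \code{targetLenS}
#' seconds (default 60, i.e. fifteen 4-s epochs per segment).
#'
#' @param x an [EpochedRecording-class].
#' @param targetLenS target segment length in seconds; must be an exact
#'   multiple of the current epoch length, and the epoch count must fill at
#'   least one whole segment.
#' @return an [EpochedRecording-class] with fewer, longer epochs.
#' @export
concatenateEpochs <- function(x, targetLenS = 60) {
  stopifnot(is(x, "EpochedRecording"))
  epochLenS <- dim(x@data)[2L] / x@fs
  k <- targetLenS / epochLenS
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf("target length %g s is not a multiple of the %g s epochs",
                 targetLenS, epochLenS))
  k <- as.integer(round(k))
  nOut <- dim(x@data)[3L] %/% k
  if (nOut < 1L)
    stop(sprintf(
      "%d epochs of %g s cover %g s < target %g s; cannot concatenate",
      dim(x@data)[3L], epochLenS, dim(x@data)[3L] * epochLenS, targetLenS))
  message(sprintf("concatenating %d groups of %d consecutive epochs", nOut, k))
  a <- array(NA_real_, dim = c(dim(x@data)[1L], dim(x@data)[2L] * k, nOut))
  for (g in seq_len(nOut)) {
    idx <- ((g - 1L) * k + 1L):(g * k)
    a[, , g] <- matrix(aperm(x@data[, , idx, drop = FALSE], c(2L, 3L, 1L)),
                       nrow = dim(x@data)[2L] * k) |> t()
  }
  out <- x
  out@data <- a
  validObject(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
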