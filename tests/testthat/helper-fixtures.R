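# Small in-code fixtures shared across test files.

# sinusoid recording: one channel, continuous
sinusoidMatrix <- function(freq, fs, durS, amp = 1, phase = 0) {
  t <- seq_len(fs * durS) / fs
  matrix(amp * sin(2 * pi * freq * t + phase), nrow = 1)
}

# symmetric random weight matrix with continuous weights in (0, 1)
randomWeightMatrix <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w <- w + t(w)
  dimnames(w) <- list(sprintf("ch%02d", 1:n), sprintf("ch%02d", 1:n))
  w
}

# brute-force maximum spanning tree by enumerating all (n-1)-edge subsets;
# spanning/acyclicity checked with a tiny union-find, independent of Kruskal's
# edge ordering in the package
enumerateMaxTreeWeight <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  combos <- utils::combn(nrow(ut), n - 1)
  best <- -Inf
  for (k in seq_len(ncol(combos))) {
    sel <- ut[combos[, k], , drop = FALSE]
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    acyclic <- TRUE
    for (e in seq_len(nrow(sel))) {
      ra <- find(sel[e, 1]); rb <- find(sel[e, 2])
      if (ra == rb) { acyclic <- FALSE; break }
      parent[ra] <- rb
    }
    if (!acyclic) next
    best <- max(best, sum(w[sel]))
  }
  best
}

# two-way mean squares via stats::aov (independent ANOVA oracle)
aovMeanSquares <- function(y) {
  df <- data.frame(value = as.vector(y),
                   subject = factor(rep(seq_len(nrow(y)), ncol(y))),
                   session = factor(rep(seq_len(ncol(y)), each = nrow(y))))
  tab <- summary(stats::aov(value ~ subject + session, data = df))[[1]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  ms
}

# naive loop-based estimator oracles
pliLoop <- function(px, py) {
  s <- 0
  for (t in seq_along(px)) {
    d <- px[t] - py[t]
    d <- (d + pi) %% (2 * pi) - pi
    if (d == -pi) d <- pi
    s <- s + sign(d)
  }
  abs(s / length(px))
}

peLoop <- function(x, m, tau) {
  nw <- length(x) - (m - 1) * tau
  pats <- character(nw)
  for (w in seq_len(nw)) {
    v <- x[w + (0:(m - 1)) * tau]
    r <- integer(m)
    for (i in seq_len(m)) {
      r[i] <- 1 + sum(v < v[i]) + sum(v[seq_len(i - 1)] == v[i])
    }
    pats[w] <- paste(r, collapse = "-")
  }
  p <- table(pats) / nw
  -sum(p * log(p)) / log(factorial(m))
}

# tiny epoched recording from a continuous matrix, alpha-filtered
alphaRecording <- function(x, fs, nEpochs, epochLenS, ...) {
  filt <- bandpass(x, canonicalBands()$alpha, fs = fs)
  segmentEpochs(filt, fs = fs, epochLenS = epochLenS, nEpochs = nEpochs,
                band = canonicalBands()$alpha, ...)
}
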