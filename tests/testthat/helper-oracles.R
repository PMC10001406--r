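# Independent reference implementations used as oracles.  These are written
# from the definitions, deliberately with different constructions than the
# package code paths they check.

# --- brute-force max-interval burst checker -------------------------------
# Enumerates every maximal candidate window by set predicates, then applies
# the merge and filter rules to a fixpoint.
bruteForceBursts <- function(train, params = defaultBurstParams()) {
  n <- length(train)
  if (n < 2L) return(data.frame(startIndex = integer(), endIndex = integer()))
  isi <- diff(train)
  openable <- which(isi <= params@maxStartISI)
  # maximal windows: start at an openable ISI not already inside an earlier
  # candidate; extend while ISIs stay below the end threshold
  cand <- list()
  covered <- 0L
  for (i in openable) {
    if (i <= covered) next
    j <- i + 1L
    while (j <= n - 1L && isi[j] <= params@maxEndISI) j <- j + 1L
    cand[[length(cand) + 1L]] <- c(i, j)
    covered <- j
  }
  if (!length(cand)) {
    return(data.frame(startIndex = integer(), endIndex = integer()))
  }
  M <- do.call(rbind, cand)
  # merge any adjacent pair with gap < minIBI, repeat to fixpoint
  repeat {
    if (nrow(M) < 2L) break
    gaps <- train[M[-1L, 1L]] - train[M[-nrow(M), 2L]]
    k <- which(gaps < params@minIBI)
    if (!length(k)) break
    k <- k[1L]
    M[k, 2L] <- M[k + 1L, 2L]
    M <- M[-(k + 1L), , drop = FALSE]
  }
  dur <- train[M[, 2L]] - train[M[, 1L]]
  cnt <- M[, 2L] - M[, 1L] + 1L
  keep <- dur >= params@minDuration & cnt >= params@minSpikes
  data.frame(startIndex = M[keep, 1L], endIndex = M[keep, 2L])
}

# random bursty-ish test train (mixture of tight clusters and loose spikes)
randomTrain <- function(maxSpikes = 50) {
  n <- sample.int(maxSpikes + 1L, 1L) - 1L
  if (n == 0L) return(numeric())
  gaps <- sample(c(
    stats::runif(n, 0.01, 0.12),     # burst-like
    stats::runif(n, 0.1, 0.8),       # ambiguous / IBI-scale
    stats::rexp(n, 2)                # background
  ), n)
  cumsum(gaps)
}

# --- segment-wise SPIKE-distance oracle -----------------------------------
# Literal per-segment computation: for every segment between consecutive
# merged (edge-augmented) spikes, the corner quantities are held fixed and
# the piecewise-linear dissimilarity is integrated by the trapezoid rule on
# its two endpoint limits.
oracleSpikeDistance <- function(a, b, interval) {
  t0 <- interval[1]; t1 <- interval[2]
  sa <- unique(c(t0, a[a > t0 & a < t1], t1))
  sb <- unique(c(t0, b[b > t0 & b < t1], t1))
  allt <- sort(unique(c(sa, sb)))
  nearest <- function(x, s) min(abs(s - x))
  total <- 0
  Svals <- function(t, iP1, iP2) {
    tP1 <- sa[iP1]; tF1 <- sa[iP1 + 1L]
    tP2 <- sb[iP2]; tF2 <- sb[iP2 + 1L]
    dP1 <- nearest(tP1, sb); dF1 <- nearest(tF1, sb)
    dP2 <- nearest(tP2, sa); dF2 <- nearest(tF2, sa)
    x1 <- tF1 - tP1; x2 <- tF2 - tP2
    S1 <- (dP1 * (tF1 - t) + dF1 * (t - tP1)) / x1
    S2 <- (dP2 * (tF2 - t) + dF2 * (t - tP2)) / x2
    (S1 * x2 + S2 * x1) / (2 * ((x1 + x2) / 2)^2)
  }
  for (k in seq_len(length(allt) - 1L)) {
    lo <- allt[k]; hi <- allt[k + 1L]
    if (hi <= lo) next
    iP1 <- max(which(sa <= lo)); iP1 <- min(iP1, length(sa) - 1L)
    iP2 <- max(which(sb <= lo)); iP2 <- min(iP2, length(sb) - 1L)
    # with the corner indices held fixed these are the one-sided limits
    sLo <- Svals(lo, iP1, iP2)
    sHi <- Svals(hi, iP1, iP2)
    total <- total + (sLo + sHi) / 2 * (hi - lo)
  }
  total / (t1 - t0)
}

randomPoissonTrain <- function(n, interval) {
  sort(stats::runif(n, interval[1], interval[2]))
}

# --- snippet stack builder for waveform tests -----------------------------
templateSnippets <- function(template, n, noiseSd = 5e-6, len = 49L,
                             alignAt = 19L, flip = 1, voltsPerSD = 5e-6) {
  base <- numeric(len)
  offs <- seq_along(template@shape) - template@troughIndex
  idx <- alignAt + offs
  ok <- idx >= 1L & idx <= len
  base[idx[ok]] <- template@shape[ok] * template@amplitude * voltsPerSD * flip
  t(vapply(seq_len(n), function(i) base + stats::rnorm(len, 0, noiseSd),
           numeric(len)))
}
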