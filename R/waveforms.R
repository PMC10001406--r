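#' Assign detected spikes on one channel to units
#'
#' Density-mode (valley-seeking) unit assignment in the spirit of the
#' classic extracellular sorters: snippets are projected onto their top two
#' principal axes, the local density is smoothed with a Gaussian kernel
#' whose bandwidth is a Parzen-style multiplier times the mean distance to
#' the sqrt(n)-th nearest neighbour, and every point hill-climbs (mean
#' shift) to its density mode; points sharing a mode form a unit.  With the
#' default multiplier of 2.0 a single noisy cluster stays one unit, while
#' well-separated clusters (for example opposite-polarity templates)
#' resolve into distinct modes.
#'
#' Duplicate clusters — the pair produced when one biphasic spike triggers
#' both detection thresholds — are merged afterwards: two units whose mean
#' waveforms have a normalized cross-correlation above `mergeCorrelation`
#' at the best alignment lag and whose spike times coincide within
#' `coincidenceWindow` are treated as one unit.
#'
#' @param snippets numeric matrix, one aligned snippet per row.
#' @param times optional spike times (s) parallel to the rows, used by the
#'   duplicate-merge rule.
#' @param parzenMultiplier kernel bandwidth multiplier (default 2.0).
#' @param minSnippets channels with fewer snippets are excluded from
#'   waveform analysis (default 10, the active-channel floor); returns
#'   `NULL`.
#' @param mergeCorrelation,coincidenceWindow duplicate-merge thresholds.
#' @return list with `labels` (integer unit per snippet), `nUnits`, and
#'   `modes` (mode coordinates in PC space), or `NULL` when the channel is
#'   excluded.
#' @export
assignUnits <- function(snippets, times = NULL, parzenMultiplier = 2.0,
                        minSnippets = 10, mergeCorrelation = 0.95,
                        coincidenceWindow = 0.5e-3) {
  n <- nrow(snippets)
  if (is.null(n) || n < minSnippets) return(NULL)
  pc <- stats::prcomp(snippets, center = TRUE, rank. = 2L)
  X <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]

  # bandwidth: Parzen multiplier x mean distance to the k-th nearest
  # neighbour (k ~ sqrt(n)); smooths sampling noise within a cluster but
  # not the gap between separated clusters
  D <- as.matrix(stats::dist(X))
  k <- max(2L, ceiling(sqrt(n)))
  dk <- apply(D, 1L, function(r) sort(r)[k])
  h <- parzenMultiplier * mean(dk)
  if (h <= 0) h <- 1e-12

  # joint mean-shift iteration of all points
  Y <- X
  for (iter in seq_len(300L)) {
    W <- exp(-0.5 * (.crossDist2(Y, X)) / h^2)
    Ynew <- (W %*% X) / rowSums(W)
    delta <- max(abs(Ynew - Y))
    Y <- Ynew
    if (delta < 1e-8 * h) break
  }

  # group converged points into modes within h/2
  labels <- integer(n)
  modes <- NULL
  for (i in seq_len(n)) {
    if (is.null(modes)) {
      modes <- Y[i, , drop = FALSE]
      labels[i] <- 1L
      next
    }
    d2 <- rowSums(sweep(modes, 2L, Y[i, ])^2)
    jm <- which.min(d2)
    if (sqrt(d2[jm]) < h / 2) {
      labels[i] <- jm
    } else {
      modes <- rbind(modes, Y[i, ])
      labels[i] <- nrow(modes)
    }
  }

  # duplicate-cluster merge
  res <- .mergeDuplicateUnits(snippets, labels, times,
                              mergeCorrelation, coincidenceWindow)
  list(labels = res$labels, nUnits = res$nUnits, modes = modes)
}

.crossDist2 <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}

.mergeDuplicateUnits <- function(snippets, labels, times,
                                 mergeCorrelation, coincidenceWindow) {
  relabel <- function(l) as.integer(factor(l))
  labels <- relabel(labels)
  nu <- max(labels)
  if (nu < 2L) return(list(labels = labels, nUnits = nu))
  repeat {
    nu <- max(labels)
    merged <- FALSE
    means <- lapply(seq_len(nu), function(u)
      colMeans(snippets[labels == u, , drop = FALSE]))
    for (u in seq_len(nu - 1L)) {
      for (v in seq.int(u + 1L, nu)) {
        if (.maxLagCorrelation(means[[u]], means[[v]]) <= mergeCorrelation)
          next
        if (!is.null(times)) {
          tu <- sort(times[labels == u])
          tv <- sort(times[labels == v])
          fu <- mean(.nearestDist(tu, tv) <= coincidenceWindow)
          fv <- mean(.nearestDist(tv, tu) <= coincidenceWindow)
          if (min(fu, fv) < 0.5) next
        }
        labels[labels == v] <- u
        labels <- relabel(labels)
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  list(labels = labels, nUnits = max(labels))
}

# normalized cross-correlation maximized over alignment lags
.maxLagCorrelation <- function(a, b, maxLag = NULL) {
  L <- length(a)
  if (is.null(maxLag)) maxLag <- L %/% 2
  best <- -1
  for (lag in -maxLag:maxLag) {
    ia <- max(1L, 1L + lag):min(L, L + lag)
    ib <- ia - lag
    if (length(ia) < 4L) next
    sa <- a[ia]; sb <- b[ib]
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) next
    best <- max(best, stats::cor(sa, sb))
  }
  best
}

#' Mean waveform and trough-to-peak duration of a unit
#'
#' Pointwise mean and SD over the unit's aligned snippets; the width is
#' measured on the mean waveform as (index of the global maximum after the
#' global minimum − index of the global minimum) / sampling rate, the
#' trough-to-subsequent-peak convention of extracellular negative-first
#' waveforms.
#'
#' @param snippets numeric matrix, aligned snippets of one unit.
#' @param samplingRate Hz.
#' @return list with `meanWaveform`, `sdWaveform`, `troughIndex`,
#'   `peakIndex`, `peakTroughUs` (microseconds) and `measurable` (FALSE
#'   when no post-trough maximum lies inside the window, in which case
#'   `peakTroughUs` is `NA`).
#' @export
meanWaveformPtd <- function(snippets, samplingRate) {
  if (is.null(nrow(snippets)) || nrow(snippets) < 1L)
    stop("at least one snippet required")
  m <- colMeans(snippets)
  s <- apply(snippets, 2L, stats::sd)
  iTrough <- which.min(m)
  post <- m[iTrough:length(m)]
  iPeak <- iTrough + which.max(post) - 1L
  measurable <- iPeak > iTrough && iPeak < length(m)
  ptd <- if (measurable) (iPeak - iTrough) / samplingRate * 1e6 else NA_real_
  list(meanWaveform = m, sdWaveform = s, troughIndex = iTrough,
       peakIndex = iPeak, peakTroughUs = ptd, measurable = measurable)
}

#' Classify a unit as excitatory or inhibitory by waveform width
#'
#' Narrow-spiking units (trough-to-peak below the threshold) are labelled
#' putative inhibitory, broad-spiking units excitatory.  A width exactly at
#' the threshold is assigned to excitatory and flagged, since the strict
#' inequalities of the published rule leave equality undefined.
#'
#' @param peakTroughUs trough-to-peak duration in microseconds.
#' @param threshold classification boundary in microseconds (default 280).
#' @return list with `label` (`"excitatory"`/`"inhibitory"`) and
#'   `boundary` (TRUE when exactly at the threshold).
#' @examples
#' classifyEI(220)$label  # inhibitory
#' classifyEI(380)$label  # excitatory
#' @export
classifyEI <- function(peakTroughUs, threshold = 280) {
  if (is.na(peakTroughUs) || peakTroughUs <= 0)
    stop("peakTroughUs must be positive")
  if (peakTroughUs < threshold) {
    list(label = "inhibitory", boundary = FALSE)
  } else {
    list(label = "excitatory", boundary = peakTroughUs == threshold)
  }
}

#' Percent excitatory units on a device
#'
#' @param labels character vector of per-unit `"excitatory"`/
#'   `"inhibitory"` labels.
#' @return percent excitatory in [0, 100]; `NA` for zero units.
#' @export
deviceEIRatio <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_real_)
  100 * sum(labels == "excitatory") / length(labels)
}

#' Waveform-based unit table for one recording
#'
#' Detects, snips, sorts and classifies every channel of a (typically
#' short) recording, producing the per-unit table feeding the E/I ratio
#' analysis.
#'
#' @param recording an [MEARecording-class].
#' @param params a [DetectionParams-class].
#' @param threshold E/I classification boundary, microseconds.
#' @param minSnippets per-channel snippet floor for unit analysis.
#' @return data.frame with one row per unit: `channel`, `unit`, `nSpikes`,
#'   `peakTroughUs`, `eiLabel`, `boundary`.
#' @export
classifyRecordingUnits <- function(recording, params = detectionParams(),
                                   threshold = 280, minSnippets = 10) {
  fs <- recording@samplingRate
  rows <- list()
  for (ch in seq_len(ncol(recording@signal))) {
    f <- .zeroPhaseHighpass(recording@signal[, ch], params@highpassCutoff, fs)
    sigma <- estimateNoiseSigma(f)
    ev <- detectSpikes(f, sigma, params, fs)
    sn <- extractSnippets(f, ev, params, fs)
    if (nrow(sn$snippets) < minSnippets) next
    au <- assignUnits(sn$snippets, sn$events$time,
                      minSnippets = minSnippets)
    if (is.null(au)) next
    for (u in seq_len(au$nUnits)) {
      sub <- sn$snippets[au$labels == u, , drop = FALSE]
      mw <- meanWaveformPtd(sub, fs)
      if (!mw$measurable) next
      cl <- classifyEI(mw$peakTroughUs, threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = recording@channelIds[ch], unit = u, nSpikes = nrow(sub),
        peakTroughUs = mw$peakTroughUs, eiLabel = cl$label,
        boundary = cl$boundary, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(channel = character(), unit = integer(),
                      nSpikes = integer(), peakTroughUs = numeric(),
                      eiLabel = character(), boundary = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
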