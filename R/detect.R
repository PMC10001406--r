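#' Spike detection parameters
#'
#' Defaults: 300 Hz high-pass, dual +/-8 sigma thresholds, 1 ms dead time,
#' 0.5 ms duplicate-collapse window, and a 0.6 ms pre / 1.0 ms post
#' trough-aligned snippet window (wide enough to contain both the 220 us
#' and 380 us trough-to-peak classes).
#'
#' @param highpassCutoff Hz.
#' @param thresholdMultiplier noise-SD multiples.
#' @param deadTime,dedupeWindow,snippetPre,snippetPost seconds.
#' @return a validated [DetectionParams-class].
#' @export
detectionParams <- function(highpassCutoff = 300, thresholdMultiplier = 8,
                            deadTime = 1e-3, dedupeWindow = 0.5e-3,
                            snippetPre = 0.6e-3, snippetPost = 1.0e-3) {
  new("DetectionParams",
      highpassCutoff = highpassCutoff,
      thresholdMultiplier = thresholdMultiplier,
      deadTime = deadTime, dedupeWindow = dedupeWindow,
      snippetPre = snippetPre, snippetPost = snippetPost)
}

#' Threshold spike detection on one filtered channel
#'
#' Dual-threshold detection at +/- k sigma: each contiguous supra-threshold
#' excursion is localized to its extremum sample (stable alignment for
#' waveform averaging), opposite-polarity event pairs within the dedupe
#' window are collapsed to the larger-magnitude one (one biphasic spike
#' crossing both thresholds yields a single event), and events closer than
#' the dead time are suppressed keeping the earlier event.
#'
#' @param x filtered channel signal, volts.
#' @param sigma channel noise SD, volts (see [estimateNoiseSigma()]).
#' @param params a [DetectionParams-class].
#' @param samplingRate Hz.
#' @return data.frame with columns `time` (s, extremum sample), `sampleIndex`,
#'   `polarity` (+1/-1) and `amplitude` (volts, signed), sorted by time.
#' @export
detectSpikes <- function(x, sigma, params = detectionParams(),
                         samplingRate) {
  if (sigma <= 0) stop("sigma must be positive")
  thr <- params@thresholdMultiplier * sigma
  empty <- data.frame(time = numeric(), sampleIndex = integer(),
                      polarity = integer(), amplitude = numeric())
  supra <- abs(x) >= thr
  if (!any(supra)) return(empty)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runIdx <- which(r$values)
  idx <- vapply(runIdx, function(k) {
    s <- starts[k]
    s + which.max(abs(x[s:ends[k]])) - 1L
  }, integer(1))
  amp <- x[idx]
  ev <- data.frame(time = (idx - 1L) / samplingRate, sampleIndex = idx,
                   polarity = ifelse(amp >= 0, 1L, -1L), amplitude = amp)
  ev <- ev[order(ev$time), , drop = FALSE]

  # collapse +/- duplicate pairs from the dual thresholds
  if (nrow(ev) > 1L && params@dedupeWindow > 0) {
    keep <- rep(TRUE, nrow(ev))
    i <- 1L
    while (i < nrow(ev)) {
      j <- i + 1L
      if (keep[i] &&
          ev$time[j] - ev$time[i] <= params@dedupeWindow &&
          ev$polarity[j] != ev$polarity[i]) {
        drop <- if (abs(ev$amplitude[i]) >= abs(ev$amplitude[j])) j else i
        keep[drop] <- FALSE
        i <- if (drop == j) j + 1L else j
      } else {
        i <- j
      }
    }
    ev <- ev[keep, , drop = FALSE]
  }

  # dead-time enforcement, keeping the earlier event
  if (nrow(ev) > 1L && params@deadTime > 0) {
    keep <- rep(TRUE, nrow(ev))
    last <- ev$time[1L]
    for (i in 2L:nrow(ev)) {
      if (ev$time[i] - last < params@deadTime) {
        keep[i] <- FALSE
      } else {
        last <- ev$time[i]
      }
    }
    ev <- ev[keep, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' Extract trough-aligned waveform snippets
#'
#' @param x filtered channel signal, volts.
#' @param events data.frame from [detectSpikes()].
#' @param params a [DetectionParams-class] (snippet window).
#' @param samplingRate Hz.
#' @return list with `snippets` (matrix, one row per retained event),
#'   `events` (the retained rows) and `nDropped` (events too close to the
#'   recording boundary for a full snippet).
#' @export
extractSnippets <- function(x, events, params = detectionParams(),
                            samplingRate) {
  nPre <- round(params@snippetPre * samplingRate)
  nPost <- round(params@snippetPost * samplingRate)
  len <- nPre + nPost + 1L
  ok <- events$sampleIndex - nPre >= 1L &
    events$sampleIndex + nPost <= length(x)
  kept <- events[ok, , drop = FALSE]
  snips <- matrix(0, nrow(kept), len)
  for (i in seq_len(nrow(kept))) {
    snips[i, ] <- x[(kept$sampleIndex[i] - nPre):(kept$sampleIndex[i] + nPost)]
  }
  list(snippets = snips, events = kept, nDropped = sum(!ok))
}

#' Detect spikes on every channel of a recording
#'
#' Convenience wrapper: high-pass filters each channel, estimates its noise
#' SD, runs [detectSpikes()], and collects per-channel trains.
#'
#' @param recording an [MEARecording-class].
#' @param params a [DetectionParams-class].
#' @return a [SpikeTrains-class] with per-channel metadata
#'   (`sigma`, `nEvents`) in `@metadata`.
#' @export
detectRecording <- function(recording, params = detectionParams()) {
  fs <- recording@samplingRate
  dur <- nrow(recording@signal) / fs
  trains <- vector("list", ncol(recording@signal))
  sigmas <- numeric(ncol(recording@signal))
  for (ch in seq_along(trains)) {
    f <- .zeroPhaseHighpass(recording@signal[, ch], params@highpassCutoff, fs)
    sigmas[ch] <- estimateNoiseSigma(f)
    ev <- detectSpikes(f, sigmas[ch], params, fs)
    trains[[ch]] <- ev$time
  }
  new("SpikeTrains", trains = trains, interval = c(0, dur),
      channelIds = recording@channelIds,
      metadata = c(recording@metadata,
                   list(sigma = sigmas,
                        nEvents = vapply(trains, length, integer(1)))))
}
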