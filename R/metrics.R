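#' Active-channel census
#'
#' A channel counts as active when it registers at least `minSpikes` spikes
#' over the recording — the conventional "at least 10 spikes per 10 min"
#' census rule.  The threshold is an absolute count by default; set
#' `rateScaled = TRUE` to scale it to a non-600 s recording length.
#'
#' @param trains a [SpikeTrains-class] or list of spike-time vectors.
#' @param minSpikes census threshold (default 10).
#' @param rateScaled logical; if `TRUE`, the threshold becomes
#'   `minSpikes * duration / 600`.
#' @param duration recording length in seconds (required for lists when
#'   `rateScaled = TRUE`).
#' @return list with `active` (logical mask), `percentActive` and
#'   `nActive`.
#' @examples
#' computeActiveChannels(list(1:10 / 10, 1:9 / 10))  # 10 spikes in, 9 out
#' @export
computeActiveChannels <- function(trains, minSpikes = 10,
                                  rateScaled = FALSE, duration = NULL) {
  tl <- if (is(trains, "SpikeTrains")) trains@trains else trains
  if (length(tl) == 0L) stop("zero channels")
  if (is(trains, "SpikeTrains") && is.null(duration))
    duration <- diff(trains@interval)
  thr <- minSpikes
  if (rateScaled) {
    if (is.null(duration)) stop("duration required for rate-scaled threshold")
    thr <- minSpikes * duration / 600
  }
  counts <- vapply(tl, length, integer(1))
  active <- counts >= thr
  list(active = active,
       percentActive = 100 * sum(active) / length(active),
       nActive = sum(active))
}

#' Mean firing rate of one electrode
#'
#' @param train spike times in seconds.
#' @param duration recording length in seconds.
#' @return rate in Hz (`count / duration`).
#' @export
perElectrodeRate <- function(train, duration) {
  if (duration <= 0) stop("duration must be positive")
  length(train) / duration
}

#' Aggregate per-electrode features to one device-session summary
#'
#' Device-level statistics are unweighted means over the active electrodes
#' only; burst features are additionally restricted to active electrodes
#' that contain at least one burst (no zero-imputation), with the count of
#' contributing electrodes recorded.  With no active electrodes the means
#' are `NA` and `percentActive` is 0.
#'
#' @param features data.frame with one row per channel and columns
#'   `rate`, `pctSpikesInBursts`, `meanBurstDuration`, `meanWithinBurstISI`,
#'   `nBursts` (as produced by [summarizeSession()] internals).
#' @param active logical per-channel mask from [computeActiveChannels()].
#' @param synchrony device-level synchrony value (or `NA`).
#' @param meta named list of identifying fields (device, session, culture,
#'   condition) copied into the row.
#' @return one-row data.frame (a device-session summary).
#' @export
aggregateDevice <- function(features, active, synchrony = NA_real_,
                            meta = list()) {
  stopifnot(nrow(features) == length(active))
  nActive <- sum(active)
  act <- features[active, , drop = FALSE]
  withBursts <- act[!is.na(act$nBursts) & act$nBursts > 0L, , drop = FALSE]
  row <- data.frame(
    device = meta$device %||% NA_character_,
    session = meta$session %||% NA_real_,
    culture = meta$culture %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    percentActive = 100 * nActive / length(active),
    meanRate = if (nActive) mean(act$rate) else NA_real_,
    pctSpikesInBursts = if (nActive) mean(act$pctSpikesInBursts) else NA_real_,
    meanBurstDuration = if (nrow(withBursts))
      mean(withBursts$meanBurstDuration) else NA_real_,
    meanWithinBurstISI = if (nrow(withBursts))
      mean(withBursts$meanWithinBurstISI) else NA_real_,
    synchrony = synchrony,
    nActive = nActive,
    nBurstingElectrodes = nrow(withBursts),
    stringsAsFactors = FALSE
  )
  rownames(row) <- NULL
  row
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize one device-session from spike trains
#'
#' Runs the census, per-electrode rates, max-interval burst analysis and
#' (optionally) multivariate SPIKE-distance synchrony, then aggregates to
#' the per-device row used by the longitudinal statistics.
#'
#' @param trains a [SpikeTrains-class] or list of spike-time vectors.
#' @param duration recording length (s); taken from the object if absent.
#' @param burstParams a [BurstParams-class].
#' @param minSpikes census threshold.
#' @param synchrony logical; compute SPIKE-distance synchrony over active
#'   electrodes (the costly step; skip when the feature is not needed).
#' @param bursts logical; run max-interval burst analysis (skip to compute
#'   census/rate features only).
#' @param meta named list of identifying fields.
#' @return one-row data.frame (see [aggregateDevice()]).
#' @export
summarizeSession <- function(trains, duration = NULL,
                             burstParams = defaultBurstParams(),
                             minSpikes = 10, synchrony = TRUE,
                             bursts = TRUE, meta = list()) {
  tl <- if (is(trains, "SpikeTrains")) trains@trains else trains
  if (is.null(duration)) {
    if (is(trains, "SpikeTrains")) duration <- diff(trains@interval)
    else stop("duration required for list input")
  }
  census <- computeActiveChannels(tl, minSpikes = minSpikes)
  feats <- do.call(rbind, lapply(tl, function(tr) {
    if (isTRUE(bursts)) {
      bs <- detectBursts(tr, burstParams)
      sm <- burstSummary(tr, bs)
      nb <- nrow(burstTable(bs))
    } else {
      sm <- list(pctSpikesInBursts = NA_real_,
                 meanBurstDuration = NA_real_,
                 meanWithinBurstISI = NA_real_)
      nb <- NA_integer_
    }
    data.frame(rate = perElectrodeRate(tr, duration),
               pctSpikesInBursts = sm$pctSpikesInBursts,
               meanBurstDuration = sm$meanBurstDuration,
               meanWithinBurstISI = sm$meanWithinBurstISI,
               nBursts = nb)
  }))
  sync <- NA_real_
  if (isTRUE(synchrony) && census$nActive >= 2L) {
    sync <- multivariateSynchrony(tl[census$active], c(0, duration))
  }
  aggregateDevice(feats, census$active, sync, meta)
}
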