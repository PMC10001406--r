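#' Configure the synthetic MEA recording generator
#'
#' Defaults describe a mature cortical culture on a 32-electrode array
#' recorded for 10 min at 30 kHz: a majority of channels active, an ~80/20
#' excitatory/inhibitory unit mixture, sparse tonic firing overlaid with
#' burst episodes that satisfy the max-interval detection criteria by
#' construction, and moderate network synchrony.
#'
#' @param nChannels,samplingRate,duration array geometry and recording grid.
#' @param pActive probability a channel carries an active unit.
#' @param pExcitatory probability an active unit is broad-spiking.
#' @param tonicRate Hz, homogeneous Poisson tonic firing.
#' @param burstOnsetRate Hz, burst-episode onset rate.
#' @param spikesPerBurst integer (min, max) spikes per burst.
#' @param withinBurstISI (min, max) of the uniform intra-burst ISI, seconds.
#' @param syncCopyProb probability a burst onset is a jittered copy of the
#'   device-wide mother process (0 = independent channels, 1 = fully
#'   network-driven bursting).
#' @param syncJitterSD SD of the copy jitter, seconds.
#' @param noiseSD recording noise SD, volts.
#' @param amplitudeSNR spike trough depth in noise-SD multiples.
#' @param seed integer seed.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nChannels = 32, samplingRate = 30000,
                             duration = 600, pActive = 0.6,
                             pExcitatory = 0.8, tonicRate = 0.4,
                             burstOnsetRate = 0.15,
                             spikesPerBurst = c(6, 10),
                             withinBurstISI = c(0.02, 0.08),
                             syncCopyProb = 0.4, syncJitterSD = 0.01,
                             noiseSD = 5e-6, amplitudeSNR = 12, seed = 1) {
  new("SimulationConfig",
      nChannels = as.integer(nChannels), samplingRate = samplingRate,
      duration = duration, pActive = pActive, pExcitatory = pExcitatory,
      tonicRate = tonicRate, burstOnsetRate = burstOnsetRate,
      spikesPerBurst = as.integer(spikesPerBurst),
      withinBurstISI = withinBurstISI, syncCopyProb = syncCopyProb,
      syncJitterSD = syncJitterSD, noiseSD = noiseSD,
      amplitudeSNR = amplitudeSNR, seed = as.integer(seed))
}

# Poisson event times on [0, duration]
.poissonTimes <- function(rate, duration) {
  if (rate <= 0) return(numeric())
  n <- stats::rpois(1L, rate * duration)
  sort(stats::runif(n, 0, duration))
}

# enforce a minimum gap between events, keeping the earlier of close pairs;
# loops only over violations (rare), not over all events
.enforceGap <- function(x, gap) {
  while (length(x) >= 2L) {
    bad <- which(diff(x) < gap)
    if (!length(bad)) break
    x <- x[-(bad[1L] + 1L)]
  }
  x
}

#' Simulate ground-truth spike trains for one device
#'
#' Two-state renewal construction: each active channel fires a homogeneous
#' Poisson tonic train superposed with burst episodes.  Burst onsets arise
#' either as jittered copies of a device-wide mother process (with
#' probability `syncCopyProb`) or as private Poisson onsets, which induces
#' tunable inter-train synchrony while preserving the per-channel onset
#' rate.  Every generated burst satisfies the max-interval detection
#' criteria by construction (ISIs below the start/end thresholds, at least
#' the minimum spike count and duration), and onsets are spaced so that
#' distinct bursts remain separated by more than the minimum inter-burst
#' interval.
#'
#' @param config a [SimulationConfig-class]; its `seed` slot drives all
#'   randomness, so a fixed config reproduces the device bit-for-bit.
#' @param activeMask optional logical vector forcing the per-channel
#'   active flags (used by the longitudinal study generator to keep channel
#'   identity consistent across sessions).
#' @param unitClass optional character vector forcing per-channel unit
#'   classes (`"excitatory"`/`"inhibitory"`).
#' @param rateScale multiplier applied to tonic and burst-onset rates
#'   (used for progressive post-LPS rate decay).
#' @return a [DeviceGroundTruth-class].
#' @export
simulateDeviceTrains <- function(config, activeMask = NULL, unitClass = NULL,
                                 rateScale = 1) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nChannels
  dur <- config@duration
  maxSpan <- (config@spikesPerBurst[2] - 1L) * config@withinBurstISI[2]
  onsetGap <- maxSpan + 0.6  # keeps distinct bursts > minIBI (0.5 s) apart
  onsetRate <- config@burstOnsetRate * rateScale
  tonicRate <- config@tonicRate * rateScale

  mother <- .enforceGap(.poissonTimes(onsetRate, dur - maxSpan), onsetGap)

  if (is.null(activeMask))
    activeMask <- stats::runif(n) < config@pActive
  if (is.null(unitClass)) {
    unitClass <- ifelse(stats::runif(n) < config@pExcitatory,
                        "excitatory", "inhibitory")
    unitClass[!activeMask] <- NA_character_
  }

  trains <- vector("list", n)
  burstIntervals <- vector("list", n)
  for (ch in seq_len(n)) {
    if (!activeMask[ch]) {
      trains[[ch]] <- numeric()
      burstIntervals[[ch]] <- matrix(numeric(), ncol = 2L,
                                     dimnames = list(NULL, c("start", "end")))
      next
    }
    copied <- mother[stats::runif(length(mother)) < config@syncCopyProb]
    if (length(copied) && config@syncJitterSD > 0)
      copied <- copied + stats::rnorm(length(copied), 0, config@syncJitterSD)
    private <- .poissonTimes((1 - config@syncCopyProb) * onsetRate,
                             dur - maxSpan)
    onsets <- sort(c(copied, private))
    onsets <- onsets[onsets >= 0 & onsets <= dur - maxSpan]
    onsets <- .enforceGap(onsets, onsetGap)

    burstSpikes <- numeric()
    ivals <- matrix(numeric(), ncol = 2L)
    if (length(onsets)) {
      kRange <- config@spikesPerBurst
      spikes <- lapply(onsets, function(t0) {
        k <- if (kRange[1] == kRange[2]) kRange[1] else
          sample(seq.int(kRange[1], kRange[2]), 1L)
        gaps <- stats::runif(k - 1L, config@withinBurstISI[1],
                             config@withinBurstISI[2])
        t0 + cumsum(c(0, gaps))
      })
      burstSpikes <- unlist(spikes)
      ivals <- cbind(onsets, vapply(spikes, max, numeric(1)))
    }
    colnames(ivals) <- c("start", "end")

    tonic <- .poissonTimes(tonicRate, dur)
    all <- rbind(
      if (length(burstSpikes)) cbind(burstSpikes, 1) else NULL,
      if (length(tonic)) cbind(tonic, 0) else NULL
    )
    if (is.null(all)) {
      trains[[ch]] <- numeric()
    } else {
      ord <- order(all[, 1L])
      all <- all[ord, , drop = FALSE]
      # drop tonic spikes that land within the detector dead time of a
      # neighbour, protecting burst spikes (their own gaps are >= 20 ms);
      # violations are rare, so iterate over them rather than all spikes
      repeat {
        if (nrow(all) < 2L) break
        bad <- which(diff(all[, 1L]) < 1e-3)
        if (!length(bad)) break
        i <- bad[1L]
        dropRow <- if (all[i + 1L, 2L] == 0) i + 1L else i
        all <- all[-dropRow, , drop = FALSE]
      }
      trains[[ch]] <- all[, 1L]
    }
    burstIntervals[[ch]] <- ivals
  }

  new("DeviceGroundTruth",
      trains = trains, active = activeMask, unitClass = unitClass,
      burstIntervals = burstIntervals, motherEvents = mother, config = config)
}

#' Synthesize one channel of continuous voltage from spike times
#'
#' Additive white Gaussian noise plus the template placed trough-aligned at
#' each spike time.  Spikes closer than the template span are superposed
#' linearly (with a warning) or rejected, per `collisions`.
#'
#' @param times spike times in seconds.
#' @param template a [WaveformTemplate-class].
#' @param duration seconds.
#' @param noiseSD noise SD in volts; the template trough depth is
#'   `template@amplitude * referenceSD` volts.
#' @param referenceSD volts corresponding to one noise-SD unit of template
#'   amplitude; defaults to `noiseSD`, or 5e-6 V for noiseless synthesis.
#' @param collisions `"superpose"` or `"error"`.
#' @return numeric vector of `round(duration * samplingRate)` volts.
#' @export
synthesizeChannelSignal <- function(times, template, duration,
                                    noiseSD = 5e-6, referenceSD = NULL,
                                    collisions = c("superpose", "error")) {
  collisions <- match.arg(collisions)
  fs <- template@samplingRate
  nSamples <- round(duration * fs)
  if (is.null(referenceSD)) referenceSD <- if (noiseSD > 0) noiseSD else 5e-6
  span <- length(template@shape) / fs
  if (length(times) > 1L && any(diff(sort(times)) < span)) {
    if (collisions == "error")
      stop("spike collision within the template span")
    warning("spikes closer than the template span; waveforms superposed")
  }
  x <- if (noiseSD > 0) stats::rnorm(nSamples, 0, noiseSD) else numeric(nSamples)
  volts <- template@amplitude * referenceSD
  shape <- template@shape * volts
  offs <- seq_along(shape) - template@troughIndex
  for (t in times) {
    centre <- round(t * fs) + 1L
    idx <- centre + offs
    ok <- idx >= 1L & idx <= nSamples
    x[idx[ok]] <- x[idx[ok]] + shape[ok]
  }
  x
}

#' Synthesize a raw multichannel recording from ground truth
#'
#' @param truth a [DeviceGroundTruth-class].
#' @param templates named list with `excitatory` and `inhibitory`
#'   [WaveformTemplate-class] elements (see [defaultTemplates()]).
#' @param noiseSD noise SD in volts (overrides the config slot if given).
#' @param collisions `"superpose"` (default) or `"error"`.
#' @return an [MEARecording-class].  Intended for short test recordings;
#'   for long recordings process channels one at a time with
#'   [synthesizeChannelSignal()].
#' @export
synthesizeRecording <- function(truth, templates = NULL, noiseSD = NULL,
                                collisions = c("superpose", "error")) {
  collisions <- match.arg(collisions)
  cfg <- truth@config
  if (is.null(noiseSD)) noiseSD <- cfg@noiseSD
  if (is.null(templates))
    templates <- defaultTemplates(cfg@samplingRate, cfg@amplitudeSNR)
  nSamples <- round(cfg@duration * cfg@samplingRate)
  sig <- matrix(0, nSamples, cfg@nChannels)
  for (ch in seq_len(cfg@nChannels)) {
    cls <- truth@unitClass[ch]
    tpl <- if (!is.na(cls)) templates[[cls]] else templates[[1L]]
    sig[, ch] <- synthesizeChannelSignal(truth@trains[[ch]], tpl,
                                         cfg@duration, noiseSD,
                                         collisions = collisions)
  }
  ids <- sprintf("ch%02d", seq_len(cfg@nChannels))
  colnames(sig) <- ids
  new("MEARecording", signal = sig, samplingRate = cfg@samplingRate,
      channelIds = ids,
      metadata = list(noiseSD = noiseSD, seed = cfg@seed))
}
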