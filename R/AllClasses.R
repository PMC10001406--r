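#' @import methods
NULL

#' Extracellular spike waveform template
#'
#' A unit-amplitude biphasic template (depolarization trough followed by an
#' after-hyperpolarization peak) on a regular sampling grid, used both to
#' synthesize raw recordings and as ground truth for trough-to-peak width
#' measurements.  The two canonical kinds mirror the narrow-spiking
#' (putative inhibitory) and broad-spiking (putative excitatory) classes of
#' cortical extracellular recordings.
#'
#' @slot kind `"narrow"` or `"broad"`.
#' @slot troughToPeak requested trough-to-peak duration in microseconds.
#' @slot amplitude trough depth in multiples of the recording noise SD.
#' @slot samplingRate sampling rate in Hz.
#' @slot shape numeric vector of unitless per-sample values; the trough has
#'   value -1, the shape decays below 1\% of the trough depth at both ends.
#' @slot troughIndex,peakIndex sample indices (1-based) of the global
#'   minimum and the following global maximum.
#'
#' @seealso [makeWaveformTemplate()]
#' @export
setClass("WaveformTemplate",
  representation(
    kind = "character",
    troughToPeak = "numeric",
    amplitude = "numeric",
    samplingRate = "numeric",
    shape = "numeric",
    troughIndex = "integer",
    peakIndex = "integer"
  )
)

setValidity("WaveformTemplate", function(object) {
  msg <- character()
  sh <- object@shape
  if (!object@kind %in% c("narrow", "broad"))
    msg <- c(msg, "kind must be 'narrow' or 'broad'")
  if (which.min(sh) != object@troughIndex)
    msg <- c(msg, "troughIndex must be the global minimum of shape")
  if (which.max(sh) != object@peakIndex)
    msg <- c(msg, "peakIndex must be the global maximum of shape")
  if (object@peakIndex <= object@troughIndex)
    msg <- c(msg, "trough must precede peak")
  measured <- (object@peakIndex - object@troughIndex) / object@samplingRate * 1e6
  halfSample <- 0.5 / object@samplingRate * 1e6
  if (abs(measured - object@troughToPeak) > halfSample + 1e-9)
    msg <- c(msg, "measured trough-to-peak deviates from requested by more than half a sample")
  depth <- abs(min(sh))
  if (abs(sh[1]) >= 0.01 * depth || abs(sh[length(sh)]) >= 0.01 * depth)
    msg <- c(msg, "shape must decay below 1% of trough depth at both ends")
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be positive")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic MEA recording generator
#'
#' Describes one simulated device-session: the channel count and sampling
#' grid, the two-state (tonic/burst) renewal firing model, the jittered
#' mother-process synchrony coupling, the excitatory/inhibitory unit
#' mixture, and the additive recording noise.
#'
#' @slot nChannels number of electrodes.
#' @slot samplingRate Hz.
#' @slot duration recording length in seconds.
#' @slot pActive probability that a channel carries an active unit.
#' @slot pExcitatory probability that an active unit is broad-spiking
#'   (excitatory); about 0.8 in rat cortex in vivo.
#' @slot tonicRate rate (Hz) of the homogeneous Poisson tonic component.
#' @slot burstOnsetRate rate (Hz) of burst-episode onsets.
#' @slot spikesPerBurst integer range (min, max) of spikes per burst.
#' @slot withinBurstISI range (s) of the uniform intra-burst inter-spike
#'   interval.
#' @slot syncCopyProb probability that a burst onset is a jittered copy of a
#'   device-wide mother event rather than a private onset.
#' @slot syncJitterSD SD (s) of the Gaussian jitter applied to copied
#'   mother events.
#' @slot noiseSD recording noise SD in volts.
#' @slot amplitudeSNR spike trough depth in multiples of noiseSD.
#' @slot seed integer random seed.
#'
#' @seealso [simulationConfig()], [simulateDeviceTrains()]
#' @export
setClass("SimulationConfig",
  representation(
    nChannels = "integer",
    samplingRate = "numeric",
    duration = "numeric",
    pActive = "numeric",
    pExcitatory = "numeric",
    tonicRate = "numeric",
    burstOnsetRate = "numeric",
    spikesPerBurst = "integer",
    withinBurstISI = "numeric",
    syncCopyProb = "numeric",
    syncJitterSD = "numeric",
    noiseSD = "numeric",
    amplitudeSNR = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  probs <- c(object@pActive, object@pExcitatory, object@syncCopyProb)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (object@tonicRate < 0 || object@burstOnsetRate < 0)
    msg <- c(msg, "rates must be non-negative")
  if (length(object@spikesPerBurst) != 2L ||
      object@spikesPerBurst[1] > object@spikesPerBurst[2])
    msg <- c(msg, "spikesPerBurst must be an increasing (min, max) pair")
  if (length(object@withinBurstISI) != 2L ||
      object@withinBurstISI[1] <= 0 ||
      object@withinBurstISI[1] > object@withinBurstISI[2])
    msg <- c(msg, "withinBurstISI must be a positive increasing (min, max) pair")
  if (object@burstOnsetRate > 0) {
    # detectability under the max-interval criteria must hold by construction
    if (object@withinBurstISI[2] >= 0.1)
      msg <- c(msg, "withinBurstISI upper bound must be < 0.1 s for detectable bursts")
    if (object@spikesPerBurst[1] < 6L)
      msg <- c(msg, "min spikes per burst must be >= 6 for detectable bursts")
    if ((object@spikesPerBurst[1] - 1L) * object@withinBurstISI[1] < 0.05)
      msg <- c(msg, "shortest generated burst must last >= 0.05 s")
    maxSpan <- (object@spikesPerBurst[2] - 1L) * object@withinBurstISI[2]
    if (1 / object@burstOnsetRate - maxSpan <= 0.5)
      msg <- c(msg, "expected inter-burst gap (1/burstOnsetRate - max span) must exceed 0.5 s")
  }
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be non-negative")
  if (object@amplitudeSNR <= 0) msg <- c(msg, "amplitudeSNR must be positive")
  if (length(msg)) msg else TRUE
})

#' Ground truth for one simulated device-session
#'
#' @slot trains list of strictly increasing spike-time vectors (s), one per
#'   channel; inactive channels hold empty vectors.
#' @slot active logical per-channel activity flags.
#' @slot unitClass per-channel `"excitatory"`/`"inhibitory"` labels
#'   (`NA` for inactive channels).
#' @slot burstIntervals list of two-column (start, end) matrices of
#'   ground-truth burst intervals in seconds.
#' @slot motherEvents device-wide mother-process event times used for
#'   synchrony coupling.
#' @slot config the [SimulationConfig-class] that generated the device.
#'
#' @export
setClass("DeviceGroundTruth",
  representation(
    trains = "list",
    active = "logical",
    unitClass = "character",
    burstIntervals = "list",
    motherEvents = "numeric",
    config = "SimulationConfig"
  )
)

setValidity("DeviceGroundTruth", function(object) {
  msg <- character()
  dur <- object@config@duration
  for (tr in object@trains) {
    if (length(tr) && (any(diff(tr) <= 0) || tr[1] < 0 || tr[length(tr)] > dur)) {
      msg <- c(msg, "spike trains must be strictly increasing within [0, duration]")
      break
    }
  }
  n <- object@config@nChannels
  if (length(object@trains) != n || length(object@active) != n ||
      length(object@unitClass) != n || length(object@burstIntervals) != n)
    msg <- c(msg, "per-channel slots must all have nChannels elements")
  if (length(msg)) msg else TRUE
})

#' Multichannel continuous extracellular recording
#'
#' @slot signal numeric matrix, samples x channels, in volts.
#' @slot samplingRate Hz.
#' @slot channelIds character channel identifiers (column names).
#' @slot metadata free-form list (device id, session, culture, ...).
#'
#' @export
setClass("MEARecording",
  representation(
    signal = "matrix",
    samplingRate = "numeric",
    channelIds = "character",
    metadata = "list"
  )
)

setValidity("MEARecording", function(object) {
  if (ncol(object@signal) != length(object@channelIds))
    return("channelIds must match the number of signal columns")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  TRUE
})

#' Per-channel spike trains over a common recording interval
#'
#' @slot trains list of strictly increasing spike-time vectors in seconds.
#' @slot interval numeric (start, end) of the common recording interval.
#' @slot channelIds character channel identifiers.
#' @slot metadata free-form list.
#'
#' @export
setClass("SpikeTrains",
  representation(
    trains = "list",
    interval = "numeric",
    channelIds = "character",
    metadata = "list"
  )
)

setValidity("SpikeTrains", function(object) {
  if (length(object@interval) != 2L || diff(object@interval) <= 0)
    return("interval must be an increasing (start, end) pair")
  if (length(object@trains) != length(object@channelIds))
    return("channelIds must match the number of trains")
  for (tr in object@trains) {
    if (length(tr)) {
      if (any(diff(tr) <= 0))
        return("spike trains must be strictly increasing")
      if (tr[1] < object@interval[1] || tr[length(tr)] > object@interval[2])
        return("spike times must lie within the interval")
    }
  }
  TRUE
})

#' Max-interval burst detection parameters
#'
#' Defaults are the five max-interval criteria in common use for cortical
#' cultures: maximum initial ISI 0.1 s, maximum end ISI 0.25 s, minimum
#' inter-burst interval 0.5 s, minimum burst duration 0.05 s, and a minimum
#' of six spikes per burst.
#'
#' @slot maxStartISI,maxEndISI,minIBI,minDuration seconds.
#' @slot minSpikes integer.
#'
#' @seealso [burstParams()], [detectBursts()]
#' @export
setClass("BurstParams",
  representation(
    maxStartISI = "numeric",
    maxEndISI = "numeric",
    minIBI = "numeric",
    minDuration = "numeric",
    minSpikes = "integer"
  )
)

setValidity("BurstParams", function(object) {
  msg <- character()
  if (object@maxStartISI > object@maxEndISI)
    msg <- c(msg, "maxStartISI must not exceed maxEndISI")
  if (any(c(object@maxStartISI, object@maxEndISI, object@minIBI,
            object@minDuration) <= 0) || object@minSpikes < 1L)
    msg <- c(msg, "all burst parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Bursts detected on one spike train
#'
#' @slot table data.frame with one row per burst: `startIndex`, `endIndex`
#'   (spike indices into the train), `tStart`, `tEnd` (s), `nSpikes`,
#'   `duration` (s).
#' @slot params the [BurstParams-class] used.
#' @slot nSpikesTrain total spike count of the source train.
#'
#' @export
setClass("BurstSet",
  representation(
    table = "data.frame",
    params = "BurstParams",
    nSpikesTrain = "integer"
  )
)

setValidity("BurstSet", function(object) {
  tb <- object@table
  need <- c("startIndex", "endIndex", "tStart", "tEnd", "nSpikes", "duration")
  if (!all(need %in% names(tb)))
    return(paste("table must contain columns:", paste(need, collapse = ", ")))
  if (nrow(tb) > 1L) {
    gaps <- tb$tStart[-1L] - tb$tEnd[-nrow(tb)]
    if (any(gaps < object@params@minIBI - 1e-12))
      return("consecutive bursts must be separated by at least minIBI")
    if (any(tb$startIndex[-1L] <= tb$endIndex[-nrow(tb)]))
      return("bursts must be disjoint and ordered")
  }
  if (nrow(tb) > 0L) {
    if (any(tb$duration < object@params@minDuration - 1e-12))
      return("every burst must last at least minDuration")
    if (any(tb$nSpikes < object@params@minSpikes))
      return("every burst must contain at least minSpikes spikes")
  }
  TRUE
})

#' Spike detection parameters
#'
#' @slot highpassCutoff high-pass corner frequency in Hz (default 300).
#' @slot thresholdMultiplier detection threshold in noise-SD multiples
#'   (default 8, applied as dual thresholds at +/- k sigma).
#' @slot deadTime minimum separation between events on one channel (s).
#' @slot dedupeWindow window (s) within which an opposite-polarity event
#'   pair is collapsed to the larger-magnitude one.
#' @slot snippetPre,snippetPost snippet extent (s) before/after the trough.
#'
#' @seealso [detectionParams()], [detectSpikes()]
#' @export
setClass("DetectionParams",
  representation(
    highpassCutoff = "numeric",
    thresholdMultiplier = "numeric",
    deadTime = "numeric",
    dedupeWindow = "numeric",
    snippetPre = "numeric",
    snippetPost = "numeric"
  )
)

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@thresholdMultiplier <= 0) msg <- c(msg, "thresholdMultiplier must be > 0")
  if (object@deadTime < 0) msg <- c(msg, "deadTime must be >= 0")
  if (object@dedupeWindow < 0) msg <- c(msg, "dedupeWindow must be >= 0")
  if (object@snippetPre < 0 || object@snippetPost <= 0)
    msg <- c(msg, "snippet window must be non-negative with positive post extent")
  if (length(msg)) msg else TRUE
})
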