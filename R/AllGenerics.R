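#' Accessors for meaflow containers
#'
#' @param x a meaflow S4 object.
#' @name accessors
NULL

#' @describeIn accessors list of per-channel spike-time vectors.
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @describeIn accessors sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @describeIn accessors channel identifiers.
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @describeIn accessors the continuous voltage matrix (samples x channels).
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @describeIn accessors data.frame of detected bursts.
#' @export
setGeneric("burstTable", function(x) standardGeneric("burstTable"))

#' @describeIn accessors recording interval (start, end) in seconds.
#' @export
setGeneric("recordingInterval", function(x) standardGeneric("recordingInterval"))

#' @describeIn accessors number of channels.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

setMethod("spikeTimes", "SpikeTrains", function(x) x@trains)
setMethod("spikeTimes", "DeviceGroundTruth", function(x) x@trains)
setMethod("samplingRate", "MEARecording", function(x) x@samplingRate)
setMethod("samplingRate", "WaveformTemplate", function(x) x@samplingRate)
setMethod("channelIds", "MEARecording", function(x) x@channelIds)
setMethod("channelIds", "SpikeTrains", function(x) x@channelIds)
setMethod("signalMatrix", "MEARecording", function(x) x@signal)
setMethod("burstTable", "BurstSet", function(x) x@table)
setMethod("recordingInterval", "SpikeTrains", function(x) x@interval)
setMethod("recordingInterval", "MEARecording", function(x)
  c(0, nrow(x@signal) / x@samplingRate))
setMethod("nChannels", "MEARecording", function(x) ncol(x@signal))
setMethod("nChannels", "SpikeTrains", function(x) length(x@trains))
setMethod("nChannels", "DeviceGroundTruth", function(x) x@config@nChannels)

setMethod("show", "WaveformTemplate", function(object) {
  cat(sprintf(
    "WaveformTemplate: %s, trough-to-peak %.0f us (grid %.1f us), amplitude %.1f SD, %d samples @ %g kHz\n",
    object@kind, object@troughToPeak,
    (object@peakIndex - object@troughIndex) / object@samplingRate * 1e6,
    object@amplitude, length(object@shape), object@samplingRate / 1e3))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0("SimulationConfig: %d channels @ %g kHz, %.0f s\n",
           "  p(active) %.2f, p(excitatory) %.2f\n",
           "  tonic %.2f Hz, burst onsets %.3f Hz, %d-%d spikes/burst, ISI %.0f-%.0f ms\n",
           "  sync copy prob %.2f (jitter %.1f ms), noise %.2g V, SNR %.0f, seed %d\n"),
    object@nChannels, object@samplingRate / 1e3, object@duration,
    object@pActive, object@pExcitatory,
    object@tonicRate, object@burstOnsetRate,
    object@spikesPerBurst[1], object@spikesPerBurst[2],
    object@withinBurstISI[1] * 1e3, object@withinBurstISI[2] * 1e3,
    object@syncCopyProb, object@syncJitterSD * 1e3,
    object@noiseSD, object@amplitudeSNR, object@seed))
})

setMethod("show", "DeviceGroundTruth", function(object) {
  n <- object@config@nChannels
  cat(sprintf(
    "DeviceGroundTruth: %d channels, %d active, %d spikes, %d ground-truth bursts\n",
    n, sum(object@active),
    sum(vapply(object@trains, length, integer(1))),
    sum(vapply(object@burstIntervals, nrow, integer(1)))))
})

setMethod("show", "MEARecording", function(object) {
  cat(sprintf("MEARecording: %d channels x %.1f s @ %g kHz\n",
              ncol(object@signal), nrow(object@signal) / object@samplingRate,
              object@samplingRate / 1e3))
})

setMethod("show", "SpikeTrains", function(object) {
  counts <- vapply(object@trains, length, integer(1))
  cat(sprintf(
    "SpikeTrains: %d channels on [%g, %g] s; %d spikes total (median %d/channel)\n",
    length(object@trains), object@interval[1], object@interval[2],
    sum(counts), as.integer(stats::median(counts))))
})

setMethod("show", "BurstSet", function(object) {
  cat(sprintf("BurstSet: %d bursts on a %d-spike train\n",
              nrow(object@table), object@nSpikesTrain))
  if (nrow(object@table)) print(utils::head(object@table, 5))
})

setMethod("show", "BurstParams", function(object) {
  cat(sprintf(
    "BurstParams: start ISI <= %.3g s, end ISI <= %.3g s, IBI >= %.3g s, duration >= %.3g s, spikes >= %d\n",
    object@maxStartISI, object@maxEndISI, object@minIBI,
    object@minDuration, object@minSpikes))
})

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf(
    "DetectionParams: high-pass %g Hz, +/-%g sigma, dead time %g ms, dedupe %g ms, snippet -%g/+%g ms\n",
    object@highpassCutoff, object@thresholdMultiplier,
    object@deadTime * 1e3, object@dedupeWindow * 1e3,
    object@snippetPre * 1e3, object@snippetPost * 1e3))
})
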