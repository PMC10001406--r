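#' Build a biphasic extracellular spike waveform template
#'
#' Constructs a unit-depth biphasic shape (negative depolarization trough
#' followed by a smaller after-hyperpolarization peak, the extracellular
#' negative-first convention) whose trough and peak fall exactly on grid
#' samples, so the requested trough-to-peak width is realized to within half
#' a sample period.  Narrow templates (~220 us) emulate narrow-spiking
#' putative inhibitory units, broad templates (~380 us) broad-spiking
#' putative excitatory units.
#'
#' @param kind `"narrow"` or `"broad"`.
#' @param troughToPeak trough-to-peak duration in microseconds; must span at
#'   least two sample periods.
#' @param samplingRate sampling rate in Hz.
#' @param amplitude trough depth in multiples of the recording noise SD.
#' @param peakRatio after-hyperpolarization peak height relative to the
#'   trough depth.
#' @return a [WaveformTemplate-class].
#' @examples
#' tpl <- makeWaveformTemplate("narrow", 220, 30000, 12)
#' tpl@peakIndex - tpl@troughIndex   # round(220e-6 * 30000) = 7 samples
#' @export
makeWaveformTemplate <- function(kind = c("narrow", "broad"), troughToPeak,
                                 samplingRate, amplitude, peakRatio = 0.5) {
  kind <- match.arg(kind)
  if (troughToPeak < 2 / samplingRate * 1e6)
    stop("troughToPeak must span at least two sample periods")
  if (amplitude <= 0) stop("amplitude must be positive")
  sep <- max(2L, as.integer(round(troughToPeak * 1e-6 * samplingRate)))
  sigmaT <- max(0.8, sep / 5)   # trough width (samples)
  sigmaP <- max(1.0, sep / 2.6) # broader AHP lobe
  pad <- ceiling(5 * max(sigmaT, sigmaP))
  len <- as.integer(2L * pad + sep + 1L)
  iTrough <- pad + 1L
  iPeak <- iTrough + sep
  i <- seq_len(len)
  shape <- -exp(-0.5 * ((i - iTrough) / sigmaT)^2) +
    peakRatio * exp(-0.5 * ((i - iPeak) / sigmaP)^2)
  # Gaussian lobes interact; rescale so the realized trough depth is exactly 1
  # and re-anchor extrema indices on the realized shape.
  shape <- shape / abs(min(shape))
  new("WaveformTemplate",
      kind = kind, troughToPeak = troughToPeak, amplitude = amplitude,
      samplingRate = samplingRate, shape = shape,
      troughIndex = which.min(shape), peakIndex = which.max(shape))
}

#' Default narrow/broad template pair
#'
#' Convenience constructor for the two-class template set used by the study
#' simulator: narrow-spiking (inhibitory) at 220 us and broad-spiking
#' (excitatory) at 380 us trough-to-peak.
#'
#' @param samplingRate Hz.
#' @param amplitude trough depth in noise-SD multiples.
#' @return named list with elements `inhibitory` and `excitatory`.
#' @export
defaultTemplates <- function(samplingRate = 30000, amplitude = 12) {
  list(
    inhibitory = makeWaveformTemplate("narrow", 220, samplingRate, amplitude),
    excitatory = makeWaveformTemplate("broad", 380, samplingRate, amplitude)
  )
}
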