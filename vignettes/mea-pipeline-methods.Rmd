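---
title: "Methods: MEA spike-train analysis in meaflow"
author: "meaflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA spike-train analysis in meaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaflow)
```

# Scope and model of the data

meaflow analyses longitudinal multichannel extracellular recordings from
in vitro neural cultures on microelectrode arrays (MEAs).  The canonical
experiment it supports records a 32-electrode array for 10 minutes at
30 kHz at a series of sessions — culture age in days in vitro (DIV) during
maturation, or hours after a neuroinflammatory challenge such as
lipopolysaccharide (LPS) — and asks how population features (fraction of
active electrodes, firing rate, bursting, network synchrony, the
excitatory/inhibitory unit mixture) evolve over those sessions and differ
between culture types.

The pipeline is organised as independent stages with explicit data
containers:

1.  **Signal processing** — zero-phase high-pass filtering, robust noise
    estimation, dual-threshold spike detection, snippet extraction.
2.  **Census and rates** — the active-electrode census and per-electrode
    firing rates, aggregated per device.
3.  **Burst analysis** — max-interval burst detection and burst features.
4.  **Synchrony** — SPIKE-distance dissimilarity across active electrodes.
5.  **Waveform classification** — unit assignment and the trough-to-peak
    width rule for putative excitatory/inhibitory labels.
6.  **Longitudinal statistics** — B-spline mixed models with
    marginal-mean contrasts and Holm adjustment.

A ground-truthed synthetic-recording generator drives validation of every
stage; it is first-class, tested code, not a fixture.

# Signal processing

**Filtering.** Spike detection operates on the 300 Hz high-passed signal.
The filter is a 4th-order Butterworth applied forward and backward
(`highpassFilter()`), so the effective magnitude response is the squared
Butterworth response and the phase is exactly zero.  Zero phase matters
here because downstream width measurements (trough-to-peak duration in
tens of microseconds) would be biased by the group delay of a causal
filter.  The implementation runs the two passes through C-level recursive
filtering with ~100 ms reflection padding at each end; it matches
`signal::filtfilt()` to better than 1e-8 away from the edges (tested)
while remaining tractable for 18-million-sample channels.

**Noise scale.** The detection threshold is expressed in units of the
noise standard deviation.  A plain SD is inflated by the spikes
themselves, so `estimateNoiseSigma()` uses the median-absolute estimator
`median(|x|)/0.6745`, which is consistent for Gaussian noise and nearly
unaffected by a few percent of large spike samples (tested against 1%
contamination).

**Detection.** `detectSpikes()` applies dual thresholds at ±k·σ with
k = 8 by default.  Each contiguous supra-threshold excursion contributes
one event at its extremum sample — the extremum, not the threshold
crossing, because the extremum is stable under noise and gives consistent
alignment for waveform averaging.  Because a biphasic spike can cross
both thresholds, an opposite-polarity pair of events within the 0.5 ms
dedupe window collapses to the larger-magnitude one.  Finally a 1 ms dead
time is enforced, keeping the earlier event.  The dead time, dedupe
window and snippet window (0.6 ms before / 1.0 ms after the trough) are
configurable defaults chosen to bracket the waveform classes of interest;
commercial detectors do not document their equivalents, so these values
are this package's own and are not claimed to match any specific product.

Detection is invariant to a global gain change of signal and threshold
together, and on synthetic devices at 12 σ spike amplitude achieves
recall ≥ 0.95 and precision ≥ 0.99 against ground truth (tested
end-to-end at full scale: 32 channels × 600 s × 30 kHz).

# Census, rates and device aggregation

An electrode is *active* when it registers at least 10 spikes in the
10-minute recording; the percentage of active electrodes is a primary
maturation read-out.  The census threshold is an absolute count by
default, with an optional rate-scaled variant for non-standard durations
(`computeActiveChannels(rateScaled = TRUE)`).

All per-electrode features are aggregated to one row per device and
session by an unweighted mean over the active electrodes only
(`aggregateDevice()`).  Burst features are additionally averaged only
over active electrodes that contain at least one burst; imputing zeros
for burstless electrodes would conflate "no bursting" with "short
bursts", and per-electrode burst statistics are conventionally reported
conditionally.  Both behaviours are available; the conditional mean is
the default and the count of contributing electrodes is recorded.

# Max-interval burst detection

`detectBursts()` implements the five-parameter max-interval method:
maximum initial ISI 0.1 s to open a burst, maximum end ISI 0.25 s to
extend it, minimum inter-burst interval 0.5 s, minimum duration 0.05 s,
minimum six spikes.  The operation order is pinned as
**detect → merge → filter**: candidates are scanned left to right, then
adjacent candidates closer than the minimum inter-burst interval
(last-spike-to-first-spike) are merged and re-measured, and only then are
the duration and spike-count minima applied.  The order matters — a
merged pair of five-spike clusters survives the six-spike filter — and
published descriptions of the commercial tools do not fully specify it,
so it is fixed here and enforced by an oracle test: on thousands of
random trains the scan output is identical to a brute-force enumeration
of maximal windows with fixpoint merging.

Burst duration is last spike minus first spike.  Per-electrode burst
features are the percentage of all spikes inside bursts, the mean burst
duration, and the mean within-burst ISI pooled across bursts.

# SPIKE-distance synchrony

Network synchrony is quantified with the time-resolved, ISI-adaptive
SPIKE-distance (Kreuz et al. 2013).  At each time *t* the distances of
the preceding and following spike of each train to the nearest spike of
the other train are linearly interpolated across the local ISI and
normalized by the mean local ISI, giving an instantaneous dissimilarity
S(t) ∈ [0, 1]; the pairwise distance is its time average.  Synchrony is
reported as one minus the mean over all unordered electrode pairs of the
pairwise distances (equivalently, by linearity, the time average of the
mean profile), computed over active electrodes only, on channel-level
trains.

Two conventions are pinned:

* **Edge handling** — auxiliary spikes are assumed at both interval
  endpoints of each train, and they participate in the nearest-spike
  distances.  This defines the profile for sparse (even empty) trains and
  makes the measure exactly 0 for identical trains.
* **Variant** — the original ISI-normalized definition is used; the
  later rate-adaptive variant is deliberately not.

S(t) is piecewise linear between consecutive spikes of the merged,
edge-augmented train pair, so the package evaluates it at segment
midpoints and integrates exactly.  Tests verify symmetry, the [0, 1]
bounds, invariance to common time rescaling, and agreement to 1e-9 with
an independently written segment-wise implementation.

# Waveform classification

Cortical extracellular units separate into narrow-spiking (putative
inhibitory) and broad-spiking (putative excitatory) classes by the width
of the mean waveform from the depolarization trough to the following
after-hyperpolarization peak.  The pipeline measures this trough-to-peak
duration on the per-unit mean waveform and classifies units with a
280 µs boundary: narrower is inhibitory, broader excitatory.  The
published form of this rule uses strict inequalities on both sides;
exact equality is assigned to excitatory and flagged
(`classifyEI()$boundary`).

Unit assignment (`assignUnits()`) replaces proprietary valley-seeking
sorters with a documented density-mode procedure of the same intent:
project snippets on their top two principal axes, smooth with a Gaussian
kernel whose bandwidth is a Parzen-style multiplier (default 2.0) times
the mean distance to the √n-th nearest neighbour, and let every point
hill-climb to its density mode (mean shift).  On sparse, low-density
channels this defaults to a single unit, matching the observation that
widely spaced electrodes at low seeding density rarely carry more than
one resolvable unit.  Duplicate clusters caused by one biphasic waveform
triggering both detection thresholds are merged when mean waveforms
correlate above 0.95 at the best alignment lag and spike times coincide
within 0.5 ms.

On labelled synthetic units at 12 σ the 220 µs / 380 µs template classes
round-trip within one sample period (16.7 µs at 30 kHz) and classify
without error; an 80/20 excitatory/inhibitory mixture is recovered
within binomial sampling error.

# Longitudinal statistics

Each feature is modelled per device and session with a linear mixed
model: fixed effects are group × cubic B-spline of session time, the
random effect is an intercept per device, fitting is by REML
(`fitSplineLme()` via lme4).  The spline basis is *saturated on the
observed session grid* — boundary knots at the first and last session
and `n_sessions − 4` interior knots at evenly spaced interior sessions —
so the fitted group trajectories can reproduce any per-session means
exactly (with five sessions this uses one interior knot).  A saturated
basis keeps marginal means at grid sessions estimable without imposing a
shape; no penalization is applied.  These choices are this package's
own: the modelling approach is standard, but spline dimension and knot
placement are rarely reported in applied work and materially affect
interpolation behaviour, so they are fixed and documented here.

Marginal means at each session are linear functions of the fixed
effects; contrasts (each later session vs the first within group, and
group differences at each session) get delta-method standard errors from
the fixed-effect covariance and t-tests on Satterthwaite degrees of
freedom (via lmerTest).  The df method matters here: a naive residual
approximation treats between-group contrasts — which compare *devices*,
the level at which the random intercept varies — as if they had
within-device precision, and simulation showed it inflates the
family-wise error above its nominal level at the 8-devices-per-arm
design; Satterthwaite assigns those contrasts roughly
devices-minus-groups degrees of freedom and restores control.  A
residual fallback (flagged per row) covers degenerate fits where the
Satterthwaite computation fails.  Within each feature the full contrast
set forms one family,
adjusted by Holm's step-down method (`stats::p.adjust`).  The package's
marginal means and standard errors are cross-checked against emmeans in
the test suite; family-wise error under a simulated null stays at or
below the nominal 5% over hundreds of replicates.

`twoSampleTtest()` provides the classical pooled-variance Student's
t-test used for single-timepoint two-group comparisons such as the
percent-excitatory difference between culture types.

Sessions where a feature is undefined (for example synchrony when fewer
than two electrodes remain active after a strong LPS response) are
dropped from that feature's fit rather than imputed.

# The synthetic-data generator

`simulateDeviceTrains()` generates ground-truthed devices from a
two-state (tonic/burst) renewal construction:

* each channel is active with probability `pActive`; active channels
  carry one unit, excitatory with probability `pExcitatory` (default
  0.8, the in vivo cortical proportion);
* tonic firing is homogeneous Poisson (`tonicRate`, default 0.4 Hz);
* burst episodes start at onset events and contain 6–10 spikes with
  uniform 20–80 ms intra-burst ISIs.  These ranges are chosen so every
  generated burst satisfies the max-interval criteria *by construction*,
  and onsets are spaced so distinct bursts stay farther apart than the
  minimum inter-burst interval; the config validator rejects parameter
  combinations that would break detectability;
* synchrony is induced by a jittered mother process: each burst onset
  is, with probability `syncCopyProb`, a Gaussian-jittered copy of a
  device-wide mother event, and otherwise private, which preserves the
  per-channel onset rate while coupling channels — the network-burst
  phenomenology of maturing cultures (per-spike copying would instead
  produce implausible spike-level duplication);
* raw voltage is additive white Gaussian noise plus a biphasic template
  (trough depth `amplitudeSNR` × noise SD, default 12) placed
  trough-aligned at each spike; collisions closer than the template span
  are superposed linearly by default.

The study-level generator (`simulateStudy()`) produces the two scenarios
the statistics stage is designed for.  **Maturation**: co- and
tri-culture arms, 8 devices each, sessions at DIV 7/10/14/17/21, with
activation probability (0.20 → 0.68), tonic rate (0.20 → 0.60 Hz),
burst-onset rate (0.04 → 0.15 Hz) and mother-copy probability
(0.15 → 0.70) rising monotonically; channel activation is *nested*
(a channel that activates stays active), giving devices a coherent
longitudinal identity.  Both culture arms share identical trajectories,
matching the finding that microglia do not alter maturation trajectories
of these features.  **LPS**: four arms (culture × condition), 4 devices
each, sessions at 0/3/12/24/48/72 h post-exposure.  Only the treated
tri-culture arm responds — each of its channels draws an exponential
death time (hazard 0.032 h⁻¹, giving ~10% surviving channels at 72 h,
the magnitude of the reported ~90% active-channel decrease) and
surviving channels' rates decay at 0.040 h⁻¹, so the rate read-out leads
the census read-out, as observed in the motivating experiments.  The
published landmarks name 3, 12 and 72 h; the intermediate sessions
complete a grid suitable for spline fitting and are this package's
choice, not the authors'.

Where a value was not dictated by the emulated study design (e.g. the
5 µV noise floor, the 12 σ amplitude, the jitter SD of 10 ms), it was
chosen once at what a practitioner would call a realistic magnitude for
planar-MEA cortical recordings and left fixed.

**What the generator does not emulate** — and hence what passing tests
do not certify about real data: electrode drift and artifacts,
non-Gaussian or correlated noise, LFP content, overlapping multi-unit
channels, amplitude variability within a unit, network bursts with
propagation structure, and any biophysics of the underlying cells.  The
generator validates the *analysis*, i.e. that each stage recovers what
it claims from data obeying its assumptions.

# Numerical choices and degenerate inputs

* Spike times are kept strictly increasing; generated spikes closer than
  the 1 ms detector dead time are resolved in favour of burst spikes.
* Trains with fewer than two spikes yield no bursts; empty burst sets
  report 0% spikes in bursts and missing burst features.
* Synchrony requires ≥ 2 active trains; otherwise it is `NA` with a
  logged reason.
* Channels with fewer than 10 snippets are excluded from waveform
  analysis; mean waveforms without a post-trough maximum inside the
  window are flagged unmeasurable rather than guessed.
* Zero-variance t-test inputs return t = 0, p = 1 when means agree.
* The mixed model tolerates singular random-effect fits (flagged); hard
  non-convergence suppresses contrasts.
* All stochastic stages are driven by explicit integer seeds; a study
  object, and every pipeline output table, is reproducible
  bit-for-bit from its configuration.

# Problem sizes used in validation

The test suite validates detection at the full canonical scale
(32 channels × 600 s × 30 kHz) once, runs the burst-detector oracle on
1000 random trains, the SPIKE-distance oracle on 100 train pairs, the
E/I recovery on a 120-channel device, 500 null replicates for
family-wise error and 100 maturation replicates for contrast power.
Exploratory examples in this vignette and the README use smaller
configurations (fewer channels, shorter recordings) purely for
readability; the statistical conventions are identical at every scale.

# A compact worked example

```{r example, eval = FALSE}
study <- simulateStudy("maturation", nDevices = 4, seed = 1,
                       baseConfig = simulationConfig(nChannels = 16,
                                                     duration = 120))
features <- summarizeStudy(study)
fit <- fitSplineLme(features, "percentActive", group = "culture")
emmContrastsHolm(fit)
```

# Known limitations

* Unit assignment is per-channel; cross-channel units and drift are out
  of scope, so the E/I read-out inherits the single-unit-per-electrode
  assumption that motivated it.
* The contrast degrees of freedom use a residual approximation;
  Satterthwaite/Kenward-Roger refinements would widen intervals slightly
  for very small device counts.
* The SPIKE-distance edge convention, while standard, makes the first
  and last fractions of a second of sparse trains contribute
  systematically; comparisons should always use equal-length intervals.
* Network-level (array-wide) burst detection is intentionally absent;
  the max-interval method here is per-electrode.
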