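test_that("pure tonic firing has Poisson spike counts", {
  cfg <- simulationConfig(nChannels = 16, duration = 600, pActive = 1,
                          tonicRate = 1, burstOnsetRate = 0, seed = 101)
  truth <- simulateDeviceTrains(cfg)
  counts <- vapply(spikeTimes(truth), length, integer(1))
  # per-channel counts ~ Poisson(600); all within 600 +/- 3*sqrt(600)
  expect_true(all(abs(counts - 600) <= 3 * sqrt(600)))
})

test_that("unit-class mixture recovers the excitatory probability", {
  cfg <- simulationConfig(nChannels = 100, duration = 10, pActive = 1,
                          pExcitatory = 0.8, tonicRate = 1,
                          burstOnsetRate = 0, seed = 202)
  truth <- simulateDeviceTrains(cfg)
  frac <- mean(truth@unitClass == "excitatory")
  ci <- qnorm(0.995) * sqrt(0.8 * 0.2 / 100)
  expect_lt(abs(frac - 0.8), ci)
})

test_that("degenerate coupling copies burst onsets across all channels", {
  cfg <- simulationConfig(nChannels = 6, duration = 120, pActive = 1,
                          syncCopyProb = 1, syncJitterSD = 0,
                          tonicRate = 0, seed = 303)
  truth <- simulateDeviceTrains(cfg)
  onsets <- lapply(truth@burstIntervals, function(m) m[, "start"])
  for (ch in 2:6) expect_equal(onsets[[ch]], onsets[[1]])
})

test_that("generated trains are strictly increasing and bounded", {
  for (seed in 1:5) {
    cfg <- simulationConfig(nChannels = 8, duration = 60, seed = seed)
    truth <- simulateDeviceTrains(cfg)
    for (tr in spikeTimes(truth)) {
      if (length(tr) > 1) expect_true(all(diff(tr) > 0))
      if (length(tr)) {
        expect_gte(min(tr), 0)
        expect_lte(max(tr), 60)
      }
    }
  }
})

test_that("every generated burst satisfies the max-interval criteria", {
  cfg <- simulationConfig(nChannels = 8, duration = 120, pActive = 1,
                          seed = 404)
  truth <- simulateDeviceTrains(cfg)
  p <- defaultBurstParams()
  for (ch in seq_len(8)) {
    tr <- spikeTimes(truth)[[ch]]
    iv <- truth@burstIntervals[[ch]]
    for (k in seq_len(nrow(iv))) {
      spk <- tr[tr >= iv[k, 1] - 1e-9 & tr <= iv[k, 2] + 1e-9]
      expect_gte(length(spk), p@minSpikes)
      expect_gte(spk[length(spk)] - spk[1], p@minDuration)
      isis <- diff(spk)
      expect_lte(isis[1], p@maxStartISI)
      expect_true(all(isis <= p@maxEndISI))
    }
    if (nrow(iv) > 1) {
      gaps <- iv[-1, 1] - iv[-nrow(iv), 2]
      expect_true(all(gaps >= p@minIBI))
    }
  }
})

test_that("fixed seeds reproduce devices and studies bit-for-bit", {
  cfg <- simulationConfig(nChannels = 4, duration = 30, seed = 7)
  t1 <- simulateDeviceTrains(cfg)
  t2 <- simulateDeviceTrains(cfg)
  expect_identical(spikeTimes(t1), spikeTimes(t2))
  s1 <- simulateStudy("maturation", nDevices = 1, seed = 5,
                      baseConfig = simulationConfig(nChannels = 4,
                                                    duration = 30))
  s2 <- simulateStudy("maturation", nDevices = 1, seed = 5,
                      baseConfig = simulationConfig(nChannels = 4,
                                                    duration = 30))
  expect_identical(lapply(s1$truths, spikeTimes),
                   lapply(s2$truths, spikeTimes))
})

test_that("infeasible generator configurations are rejected", {
  expect_error(simulationConfig(withinBurstISI = c(0.02, 0.15)), "0.1 s")
  expect_error(simulationConfig(spikesPerBurst = c(3, 10)), ">= 6")
  expect_error(simulationConfig(burstOnsetRate = 1.5), "inter-burst gap")
  expect_error(simulationConfig(pActive = 1.4), "probabilities")
})

test_that("noiseless synthesis places the template at the ground-truth sample", {
  tpl <- makeWaveformTemplate("narrow", 220, 30000, 12)
  x <- synthesizeChannelSignal(0.25, tpl, 0.5, noiseSD = 0)
  expect_equal(which.min(x), round(0.25 * 30000) + 1L)
})

test_that("noise-only synthesis has the configured SD", {
  cfg <- simulationConfig(nChannels = 1, duration = 20, pActive = 0,
                          noiseSD = 5e-6, seed = 11)
  truth <- simulateDeviceTrains(cfg)
  rec <- synthesizeRecording(truth)
  expect_lt(abs(sd(signalMatrix(rec)[, 1]) / 5e-6 - 1), 0.02)
})

test_that("colliding spikes are superposed with a warning or rejected", {
  tpl <- makeWaveformTemplate("narrow", 220, 30000, 12)
  expect_warning(synthesizeChannelSignal(c(0.1, 0.1005), tpl, 0.3,
                                         noiseSD = 0), "superposed")
  expect_error(synthesizeChannelSignal(c(0.1, 0.1005), tpl, 0.3,
                                       noiseSD = 0, collisions = "error"),
               "collision")
})

test_that("lps scenario with zero hazard and decay matches control in distribution", {
  par0 <- lpsParameters()
  par0$hazardPerHour <- 0
  par0$rateDecayPerHour <- 0
  st <- simulateStudy("lps", nDevices = 2, seed = 13,
                      baseConfig = simulationConfig(nChannels = 16,
                                                    duration = 60),
                      trajectories = par0)
  sm <- summarizeStudy(st, synchrony = FALSE)
  agg <- aggregate(percentActive ~ condition, sm, mean)
  # null effect: treated and control arms statistically indistinguishable
  expect_lt(abs(diff(agg$percentActive)), 20)
})

test_that("maturation ground truth activates monotonically", {
  st <- simulateStudy("maturation", nDevices = 2, seed = 21,
                      baseConfig = simulationConfig(nChannels = 32,
                                                    duration = 30))
  act <- vapply(st$truths, function(tr) mean(tr@active), numeric(1))
  m <- tapply(act, st$sessions$session, mean)
  expect_true(all(diff(m) > 0))
})

test_that("noiseless synthesis round-trips >=99% of spikes and bursts end-to-end", {
  fs <- 30000
  cfg <- simulationConfig(nChannels = 6, duration = 120, pActive = 1,
                          noiseSD = 0, seed = 515)
  truth <- simulateDeviceTrains(cfg)
  templates <- defaultTemplates(fs, 12)
  refSD <- 5e-6
  params <- detectionParams()
  nSpk <- 0L; nSpkHit <- 0L; nBur <- 0L; nBurHit <- 0L
  for (ch in seq_len(6)) {
    tpl <- templates[[truth@unitClass[ch]]]
    x <- synthesizeChannelSignal(truth@trains[[ch]], tpl, 120,
                                 noiseSD = 0, referenceSD = refSD)
    f <- highpassFilter(x, 300, fs)
    ev <- detectSpikes(f, refSD, params, fs)
    tt <- truth@trains[[ch]]
    hits <- vapply(tt, function(t0) any(abs(ev$time - t0) <= 1e-3),
                   logical(1))
    nSpk <- nSpk + length(tt); nSpkHit <- nSpkHit + sum(hits)
    # every ground-truth burst must be covered by a detected burst
    det <- burstTable(detectBursts(ev$time))
    iv <- truth@burstIntervals[[ch]]
    for (k in seq_len(nrow(iv))) {
      nBur <- nBur + 1L
      covered <- any(det$tStart <= iv[k, 1] + 1e-3 &
                       det$tEnd >= iv[k, 2] - 1e-3)
      nBurHit <- nBurHit + as.integer(covered)
    }
  }
  expect_gt(nSpk, 500)
  expect_gt(nBur, 20)
  expect_gte(nSpkHit / nSpk, 0.99)
  expect_gte(nBurHit / nBur, 0.99)
})
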