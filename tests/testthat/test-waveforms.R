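test_that("one noisy template yields a single unit", {
  set.seed(41)
  tpl <- makeWaveformTemplate("broad", 380, 30000, 12)
  sn <- templateSnippets(tpl, 80)
  au <- assignUnits(sn, times = seq_len(80) * 0.1)
  expect_identical(au$nUnits, 1L)
  # below the snippet floor the channel is excluded
  expect_null(assignUnits(sn[1:5, , drop = FALSE]))
})

test_that("opposite-polarity template mixture resolves into two accurate units", {
  set.seed(43)
  tplN <- makeWaveformTemplate("narrow", 220, 30000, 12)
  tplB <- makeWaveformTemplate("broad", 380, 30000, 12)
  sn <- rbind(templateSnippets(tplN, 70),
              templateSnippets(tplB, 70, flip = -1))
  truthLab <- rep(1:2, each = 70)
  # far-apart spike times so the duplicate-merge rule cannot fire
  au <- assignUnits(sn, times = c(seq_len(70) * 0.5,
                                  100 + seq_len(70) * 0.5))
  expect_identical(au$nUnits, 2L)
  tab <- table(au$labels, truthLab)
  acc <- sum(apply(tab, 2, max)) / length(truthLab)
  expect_gte(acc, 0.95)
})

test_that("duplicate +/- threshold copies of one unit are merged", {
  set.seed(47)
  tpl <- makeWaveformTemplate("broad", 380, 30000, 12)
  times <- seq_len(60) * 0.5
  # copy A aligned on the trough, copy B the same events aligned on the peak
  sep <- tpl@peakIndex - tpl@troughIndex
  a <- templateSnippets(tpl, 60, alignAt = 19L)
  b <- templateSnippets(tpl, 60, alignAt = 19L - sep)
  au <- assignUnits(rbind(a, b), times = c(times, times))
  expect_identical(au$nUnits, 1L)
})

test_that("mean waveform width measurement follows the trough-to-peak rule", {
  # trough at sample 18, peak at sample 29 at 30 kHz: 11 samples = 366.7 us
  w <- rep(0, 49)
  w[18] <- -1
  w[29] <- 0.5
  mw <- meanWaveformPtd(rbind(w, w), 30000)
  expect_equal(mw$peakTroughUs, 11 / 30000 * 1e6, tolerance = 1e-9)
  # template round-trip within one sample period
  tpl <- makeWaveformTemplate("narrow", 220, 30000, 12)
  mw <- meanWaveformPtd(templateSnippets(tpl, 30, noiseSd = 0), 30000)
  expect_lt(abs(mw$peakTroughUs - 220), 1e6 / 30000 + 1e-9)
  # gain invariance
  sn <- templateSnippets(tpl, 30)
  expect_equal(meanWaveformPtd(sn * 4.2, 30000)$peakTroughUs,
               meanWaveformPtd(sn, 30000)$peakTroughUs)
  # monotone-decreasing tail: no post-trough peak inside the window
  bad <- matrix(-seq(0.5, 1, length.out = 20), nrow = 1)
  expect_false(meanWaveformPtd(bad, 30000)$measurable)
})

test_that("the 280 us rule classifies narrow as inhibitory, broad as excitatory", {
  expect_identical(classifyEI(220)$label, "inhibitory")
  expect_identical(classifyEI(380)$label, "excitatory")
  atBoundary <- classifyEI(280)
  expect_identical(atBoundary$label, "excitatory")
  expect_true(atBoundary$boundary)
  expect_false(classifyEI(380)$boundary)
  expect_error(classifyEI(-5), "positive")
})

test_that("device E/I ratio is the excitatory percentage", {
  expect_equal(deviceEIRatio(rep(c("excitatory", "inhibitory"), c(8, 2))), 80)
  expect_equal(deviceEIRatio(rep("inhibitory", 5)), 0)
  expect_true(is.na(deviceEIRatio(character())))
})

test_that("peak-trough histogram of a 50/50 mixture is bimodal at the template widths", {
  set.seed(53)
  fs <- 30000
  tplN <- makeWaveformTemplate("narrow", 220, fs, 12)
  tplB <- makeWaveformTemplate("broad", 380, fs, 12)
  ptds <- c(
    vapply(1:40, function(i)
      meanWaveformPtd(templateSnippets(tplN, 25), fs)$peakTroughUs,
      numeric(1)),
    vapply(1:40, function(i)
      meanWaveformPtd(templateSnippets(tplB, 25), fs)$peakTroughUs,
      numeric(1))
  )
  onePeriod <- 1e6 / fs
  modeOf <- function(x) as.numeric(names(which.max(table(round(x, 1)))))
  expect_lt(abs(modeOf(ptds[1:40]) - 220), onePeriod + 1e-9)
  expect_lt(abs(modeOf(ptds[41:80]) - 380), onePeriod + 1e-9)
  # the two modes are well separated (bimodality)
  expect_gt(modeOf(ptds[41:80]) - modeOf(ptds[1:40]), 100)
  # classification at SNR 12 is perfect for these widths
  labs <- vapply(ptds, function(p) classifyEI(p)$label, character(1))
  expect_identical(labs, rep(c("inhibitory", "excitatory"), each = 40))
})

test_that("recording-level unit table recovers planted classes", {
  set.seed(59)
  cfg <- simulationConfig(nChannels = 10, duration = 40, pActive = 1,
                          tonicRate = 1.2, burstOnsetRate = 0,
                          pExcitatory = 0.5, seed = 313)
  truth <- simulateDeviceTrains(cfg)
  rec <- synthesizeRecording(truth)
  units <- classifyRecordingUnits(rec)
  expect_gt(nrow(units), 0)
  got <- units$eiLabel[match(sprintf("ch%02d", 1:10), units$channel)]
  ok <- !is.na(got)
  expect_gte(sum(ok), 8)
  expect_identical(got[ok], unname(truth@unitClass[ok]))
})
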