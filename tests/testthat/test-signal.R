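test_that("high-pass filter rejects DC and low frequencies, passes spike band", {
  fs <- 30000
  t <- seq(0, 2, by = 1 / fs)
  # DC rejection
  out <- highpassFilter(rep(0.5, length(t)), 300, fs)
  mid <- out[10000:(length(out) - 10000)]
  expect_lt(max(abs(mid)), 0.5 * 1e-6)
  # 1 kHz preserved within 5%
  out <- highpassFilter(sin(2 * pi * 1000 * t), 300, fs)
  expect_lt(abs(max(abs(out[10000:50000])) - 1), 0.05)
  # 10 Hz attenuated by >= 90%
  out <- highpassFilter(sin(2 * pi * 10 * t), 300, fs)
  expect_lt(max(abs(out[10000:50000])), 0.1)
  expect_error(highpassFilter(t, 20000, fs), "Nyquist")
})

test_that("zero-phase filtering matches the reference filtfilt away from edges", {
  set.seed(42)
  fs <- 30000
  x <- rnorm(60000) + 0.3
  mine <- highpassFilter(x, 300, fs)
  bf <- signal::butter(4, 300 / (fs / 2), type = "high")
  ref <- signal::filtfilt(bf, x)
  i <- 5000:55000
  expect_lt(max(abs(mine[i] - ref[i])), 1e-8)
})

test_that("robust noise sigma ignores spike contamination", {
  set.seed(1)
  fs <- 30000
  x <- rnorm(60 * fs, 0, 5e-6)
  expect_lt(abs(estimateNoiseSigma(x) / 5e-6 - 1), 0.01)
  expect_equal(estimateNoiseSigma(numeric(100)), 0)
  expect_error(estimateNoiseSigma(numeric(0)), "empty")
  # 1% contaminating large events inflate the plain SD but not the estimate
  xc <- x
  idx <- sample(length(xc), length(xc) * 0.01)
  xc[idx] <- xc[idx] + sample(c(-1, 1), length(idx), TRUE) * 60e-6
  expect_lt(abs(estimateNoiseSigma(xc) / 5e-6 - 1), 0.03)
  expect_gt(sd(xc) / 5e-6, 1.10)
})

test_that("spike detection finds planted templates and dedupes biphasic events", {
  set.seed(2)
  fs <- 30000
  tpl <- makeWaveformTemplate("broad", 380, fs, 12)
  times <- sort(runif(50, 0.05, 59.95))
  times <- times[c(TRUE, diff(times) > 5e-3)]
  x <- synthesizeChannelSignal(times, tpl, 60, noiseSD = 5e-6)
  f <- highpassFilter(x, 300, fs)
  sigma <- estimateNoiseSigma(f)
  ev <- detectSpikes(f, sigma, detectionParams(), fs)
  # recall: almost all planted spikes recovered within 0.2 ms
  hit <- vapply(times, function(tt) any(abs(ev$time - tt) <= 2e-4),
                logical(1))
  expect_gte(sum(hit), length(times) - 2)
  # precision: at most 1 unmatched event
  fp <- vapply(ev$time, function(tt) all(abs(times - tt) > 2e-4), logical(1))
  expect_lte(sum(fp), 1)
  # one biphasic spike crossing both thresholds gives exactly one event
  x1 <- synthesizeChannelSignal(0.25, tpl, 0.5, noiseSD = 0)
  ev1 <- detectSpikes(x1, 5e-6, detectionParams(), fs)
  expect_identical(nrow(ev1), 1L)
  expect_identical(ev1$polarity, -1L)
  # flat signal yields nothing
  expect_identical(nrow(detectSpikes(numeric(1000), 5e-6,
                                     detectionParams(), fs)), 0L)
})

test_that("detection respects dead time, threshold and gain invariance", {
  set.seed(3)
  fs <- 30000
  tpl <- makeWaveformTemplate("narrow", 220, fs, 12)
  x <- synthesizeChannelSignal(sort(runif(20, 0.1, 19.9)), tpl, 20,
                               noiseSD = 5e-6)
  f <- highpassFilter(x, 300, fs)
  sigma <- estimateNoiseSigma(f)
  p <- detectionParams()
  ev <- detectSpikes(f, sigma, p, fs)
  expect_true(all(abs(ev$amplitude) >= p@thresholdMultiplier * sigma))
  if (nrow(ev) > 1) expect_true(all(diff(ev$time) >= p@deadTime))
  # global gain rescaling leaves event times unchanged
  ev2 <- detectSpikes(f * 3.7, sigma * 3.7, p, fs)
  expect_identical(ev$time, ev2$time)
})

test_that("snippet extraction aligns troughs and drops boundary events", {
  fs <- 30000
  tpl <- makeWaveformTemplate("broad", 380, fs, 12)
  x <- synthesizeChannelSignal(c(0, 0.25), tpl, 0.5, noiseSD = 0)
  ev <- detectSpikes(x, 5e-6, detectionParams(), fs)
  sn <- extractSnippets(x, ev, detectionParams(), fs)
  # the event at t = 0 cannot support a full pre-window
  expect_identical(sn$nDropped, 1L)
  expect_identical(nrow(sn$snippets), 1L)
  p <- detectionParams()
  expect_identical(ncol(sn$snippets),
                   as.integer(round(p@snippetPre * fs) +
                                round(p@snippetPost * fs) + 1L))
  # noiseless snippet reproduces the template over the overlapping window
  tplV <- tpl@shape * 12 * 5e-6
  seg <- sn$snippets[1, ]
  iT <- which.min(seg)
  offs <- seq_along(tplV) - tpl@troughIndex
  ok <- iT + offs >= 1 & iT + offs <= length(seg)
  expect_lt(max(abs(seg[iT + offs[ok]] - tplV[ok])), 1e-12)
})
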