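test_that("multitaper state PSD localises tones and is flat for noise", {
  fs <- 100
  t <- seq(1 / fs, 20, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t)
  sp <- statePsd(tone, rep(1, length(tone)), fs)
  expect_lt(abs(sp@peakFreq - 10), 0.5)
  expect_equal(sp@onTime, 20)
  # white noise: flat within 3 dB over 3-45 Hz
  noise <- withr::with_seed(1, rnorm(30 * fs))
  spw <- statePsd(noise, rep(1, length(noise)), fs)
  sel <- spw@freqs >= 3 & spw@freqs <= 45
  expect_lt(10 * log10(max(spw@psd[sel]) / min(spw@psd[sel])), 3)
  # zero signal gives an identically zero spectrum
  spz <- statePsd(rep(0, 1000), rep(1, 1000), fs)
  expect_true(all(spz@psd == 0))
  # insufficient on-time is flagged missing
  expect_warning(out <- statePsd(tone, c(rep(1, 50), rep(0, length(tone) - 50)),
                                 fs), "flagged missing")
  expect_null(out)
})

test_that("tone power concentrates in short bursty on-segments too", {
  fs <- 100
  t <- seq(1 / fs, 60, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  # thirty 300 ms segments, mimicking thresholded burst intervals
  on <- rep(0, length(x))
  starts <- seq(100, 5900, by = 200)[1:30]
  for (s in starts) on[s:(s + 29)] <- 1
  sp <- statePsd(x, on, fs)
  expect_lt(abs(sp@peakFreq - 10), 1)
})

test_that("band power integrates the PSD over half-open canonical bands", {
  spec <- new("StateSpectrum", freqs = 0:50, psd = rep(1, 51), peakFreq = 10,
              onTime = 10)
  bp <- bandPower(spec)
  expect_equal(unname(bp), c(4, 5, 17))  # band widths for a unit PSD
  # a 10 Hz tone puts nearly everything in alpha
  fs <- 100
  t <- seq(1 / fs, 20, by = 1 / fs)
  sp <- statePsd(sin(2 * pi * 10 * t), rep(1, 2000), fs)
  bp2 <- bandPower(sp)
  expect_gt(bp2[["alpha"]], 10 * bp2[["theta"]])
  expect_gt(bp2[["alpha"]], 10 * bp2[["beta"]])
  # linear in the PSD
  spec2 <- new("StateSpectrum", freqs = spec@freqs, psd = 2 * spec@psd,
               peakFreq = 10, onTime = 10)
  expect_equal(bandPower(spec2), 2 * bp)
  # band powers never exceed the total 3-45 Hz area
  total <- ptrburst:::trapezoidArea(sp@freqs, sp@psd, 3, 45)
  expect_lte(sum(bandPower(sp)), total + 1e-12)
  expect_error(bandPower(spec, bands = list(x = c(40, 60))), "cover")
})

test_that("region summaries combine durations, peaks and rates", {
  design <- blockDesign(nBlocks = 1L)
  spec <- new("StateSpectrum", freqs = 0:50, psd = dnorm(0:50, 10, 1),
              peakFreq = 10, onTime = 10)
  bursts <- data.frame(region = "A", state = 2L,
                       onset_s = c(33, 34, 35), offset_s = c(33.3, 34.3, 35.3),
                       duration_s = c(0.3, 0.3, 0.3),
                       participant = c("p1", "p1", "p1"))
  sm <- summarizeRegion(bursts, spec, design)
  expect_equal(sm$mean_duration_s, 0.3)
  expect_equal(sm$se_duration_s, 0)
  expect_equal(sm$cycles_per_burst, 3)  # 0.3 s x 10 Hz
  # burst rate: all three bursts sit in the 7 s PTR window of one block
  expect_equal(sm$rate_ptr_hz, 3 / 7)
  expect_equal(sm$rate_task_hz, 0)
  expect_warning(out <- summarizeRegion(bursts[0, ], spec, design), "missing")
  expect_null(out)
})

test_that("TFR reconstruction is the probability-spectrum product", {
  freqs <- 0:50
  psd <- dnorm(freqs, 20, 2)
  spec <- new("StateSpectrum", freqs = freqs, psd = psd, peakFreq = 20,
              onTime = 5)
  # state always on: TFR constant in time and equal to the PSD
  recon <- reconstructTfr(matrix(1, 1, 30), list(spec))
  expect_true(all(recon$total == psd))
  # zero probability: zero TFR
  recon0 <- reconstructTfr(matrix(0, 1, 30), list(spec))
  expect_true(all(recon0$total == 0))
  # linear in both inputs
  p <- matrix(runif(30), 1)
  r1 <- reconstructTfr(p, list(spec))
  spec2 <- new("StateSpectrum", freqs = freqs, psd = 2 * psd, peakFreq = 20,
               onTime = 5)
  expect_equal(reconstructTfr(p, list(spec2))$total, 2 * r1$total)
  expect_equal(reconstructTfr(2 * p, list(spec))$total, 2 * r1$total,
               tolerance = 1e-12)
  # two states sum
  both <- reconstructTfr(rbind(p, p), list(spec, spec2))
  expect_equal(both$total, 3 * r1$total, tolerance = 1e-12)
  expect_error(reconstructTfr(p, list(spec, spec2)), "one spectrum per state")
})

test_that("burst coincidence is the windowed Jaccard index", {
  a <- c(0, 1, 1, 0, 0, 1, 0, 0)
  expect_equal(burstCoincidence(a, a), 1)
  b <- c(1, 0, 0, 1, 1, 0, 0, 1)
  expect_equal(burstCoincidence(a, b), 0)
  # self shifted beyond all burst durations: no overlap
  x <- rep(0, 100); x[10:12] <- 1; x[50:52] <- 1
  y <- c(rep(0, 5), x[1:95])
  expect_equal(burstCoincidence(x, y), 0)
  expect_equal(burstCoincidence(a, b, window = 1:4), 0)
  expect_error(burstCoincidence(a, b, window = integer()), "window")
})

test_that("model-derived PSD cross-checks the data-segment PSD", {
  run <- sixRegionRun()
  res <- run$result
  # alpha region: both routes put the peak in the alpha band
  k <- res$ptrStates[["P1"]]
  mp <- modelPsd(res$fits[["P1"]], k)
  expect_lt(abs(mp@peakFreq - res$spectra[["P1"]]@peakFreq), 3)
  expect_true(all(mp@psd >= 0))
})
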