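test_that("zero burst rates give pure unit-SD background and empty truth", {
  rs <- regionSpec("A", burstSpec(10), rateTask = 0, ratePtr = 0, rateRest = 0)
  ds <- generateDataset(list(rs), blockDesign(nBlocks = 2L), fs = 100, seed = 1)
  expect_equal(nrow(groundTruth(ds)), 0L)
  expect_equal(sd(ds@data[1, ]), 1, tolerance = 1e-12)
  expect_equal(mean(ds@data[1, ]), 0, tolerance = 1e-12)
})

test_that("burst counts follow the window-specific Poisson process", {
  # PTR-only rate 0.5/s over 16 blocks x 7 s windows: mean 56, SD sqrt(56)
  rs <- regionSpec("A", burstSpec(10), rateTask = 0, ratePtr = 0.5,
                   rateRest = 0)
  ds <- generateDataset(list(rs), blockDesign(nBlocks = 16L), fs = 100,
                        seed = 7)
  n <- nrow(groundTruth(ds))
  expect_lt(abs(n - 56), 3 * sqrt(56))
  # all bursts must fall inside PTR windows (truncation to window + duration)
  tr <- groundTruth(ds)
  tmod <- tr$onset_s %% 62
  expect_true(all(tmod >= 32 - 1e-9 & tmod <= 39 + 1e-9))
})

test_that("Poisson consistency holds across many seeds", {
  rs <- regionSpec("A", burstSpec(20), rateTask = 0.3, ratePtr = 0.3,
                   rateRest = 0.3)
  design <- blockDesign(nBlocks = 1L)
  counts <- vapply(1:200, function(s) {
    nrow(groundTruth(generateDataset(list(rs), design, fs = 100, seed = s)))
  }, 0)
  lam <- 0.3 * 62  # uniform rate over a full 62 s block
  # mean within 3 SE; merging of overlapping bursts removes a few percent
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 200) + 0.05 * lam)
})

test_that("burst durations follow the truncated normal generator", {
  rs <- regionSpec("A", burstSpec(20, meanDuration = 0.3,
                                  durationDispersion = 0.05),
                   rateTask = 0.12, ratePtr = 0.12, rateRest = 0.12)
  ds <- generateDataset(list(rs), blockDesign(nBlocks = 16L), fs = 600,
                        seed = 11)
  tr <- groundTruth(ds)
  expect_gte(nrow(tr), 100)
  expect_lt(abs(mean(tr$offset_s - tr$onset_s) - 0.3), 0.02)
})

test_that("identical seeds reproduce the dataset bit-for-bit", {
  rs <- regionSpec("A", burstSpec(15))
  d1 <- generateDataset(list(rs), blockDesign(nBlocks = 2L), fs = 200, seed = 3)
  d2 <- generateDataset(list(rs), blockDesign(nBlocks = 2L), fs = 200, seed = 3)
  d3 <- generateDataset(list(rs), blockDesign(nBlocks = 2L), fs = 200, seed = 4)
  expect_identical(d1@data, d2@data)
  expect_identical(groundTruth(d1), groundTruth(d2))
  expect_false(identical(d1@data, d3@data))
})

test_that("a bursts-only signal peaks at the carrier frequency", {
  mkds <- function(amp) {
    rs <- regionSpec("A", burstSpec(10, amplitude = amp),
                     rateTask = 0.3, ratePtr = 0.3, rateRest = 0.3)
    generateDataset(list(rs), blockDesign(nBlocks = 4L), fs = 100, seed = 9)
  }
  # same seed => identical background; the difference isolates the bursts
  burstsOnly <- mkds(3)@data[1, ] - mkds(0)@data[1, ]
  pg <- spec.pgram(ts(burstsOnly, frequency = 100), spans = 9, plot = FALSE)
  sel <- pg$freq >= 2 & pg$freq <= 45
  expect_lt(abs(pg$freq[sel][which.max(pg$spec[sel])] - 10), 1)
})

test_that("spec violations are rejected", {
  expect_error(generateDataset(list(), blockDesign(), fs = 100, seed = 1),
               "non-empty")
  expect_error(generateDataset(list(regionSpec("A", burstSpec(80))),
                               blockDesign(nBlocks = 1L), fs = 100, seed = 1),
               "Nyquist")
  expect_error(burstSpec(-5), "carrierFreq")
  expect_error(regionSpec("A", rateTask = -1), "rates")
  expect_error(blockDesign(ptrWindow = c(0, 40)), "ptrWindow")
})

test_that("dataset round-trip through the text container is lossless", {
  rs <- list(regionSpec("A", burstSpec(10)), regionSpec("B", burstSpec(20)))
  ds <- generateDataset(rs, blockDesign(nBlocks = 2L,
                                        conditionLabels = c("1-back", "2-back")),
                        fs = 200, seed = 6)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  rt <- readDataset(dir)
  expect_equal(rt@data, ds@data, tolerance = 1e-12)
  expect_equal(rt@fs, ds@fs)
  expect_equal(rt@seed, ds@seed)
  expect_equal(groundTruth(rt)$onset_s, groundTruth(ds)$onset_s)
  expect_equal(rt@design@conditionLabels, ds@design@conditionLabels)
  expect_equal(vapply(rt@regions, function(r) r@burst@carrierFreq, 0),
               c(10, 20))
  # truth CSV has one row per ground-truth burst
  truthCsv <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truthCsv), nrow(groundTruth(ds)))
  expect_named(truthCsv, c("region", "onset_s", "offset_s", "carrier_hz"))
})

test_that("corrupted sampling-rate metadata is rejected on read", {
  ds <- generateDataset(list(regionSpec("A", burstSpec(10))),
                        blockDesign(nBlocks = 1L), fs = 200, seed = 2)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  attrs <- jsonlite::read_json(file.path(dir, "attrs.json"))
  attrs$fs <- 999
  jsonlite::write_json(attrs, file.path(dir, "attrs.json"), auto_unbox = TRUE)
  expect_error(readDataset(dir), "metadata mismatch")
  file.remove(file.path(dir, "meta.json"))
  expect_error(readDataset(dir), "missing dataset file")
})
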