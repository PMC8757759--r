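# oracle for filter gain: amplitude of a filtered unit sine, edge-trimmed
sineGain <- function(freqHz, fsHz = 1024, durationS = 2, ...) {
  n <- fsHz * durationS
  t <- (seq_len(n) - 1L) / fsHz
  g <- GridGeometry(nRows = 2, nCols = 2, missing = matrix(c(1L, 1L), 1L))
  rec <- GridRecording(matrix(sin(2 * pi * freqHz * t), 3, n, byrow = TRUE),
                       fsHz = fsHz, geometry = g)
  y <- signalMatrix(bandpassFilter(rec, ...))[1L, ]
  mid <- seq.int(n %/% 4, 3 * n %/% 4)
  sqrt(2 * mean(y[mid]^2))
}

test_that("band-pass preserves in-band tones and rejects out-of-band ones", {
  expect_gte(sineGain(100), 0.95)
  expect_lte(sineGain(5), 0.1)
  # geometric-mean frequency of the 20-400 band is in the flat passband
  expect_equal(sineGain(sqrt(20 * 400)), 1, tolerance = 0.05)
  # DC is annihilated
  expect_lte(sineGain(0), 1e-3)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- sineRecording(rep(1, 64))
  expect_error(bandpassFilter(rec, 20, 512), "Nyquist")
  expect_error(bandpassFilter(rec, 0, 400), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(3)
  n <- 1024L
  g <- GridGeometry(nRows = 2, nCols = 2, missing = matrix(c(1L, 1L), 1L))
  mk <- function(m) GridRecording(m, fsHz = 1024, geometry = g)
  x <- matrix(rnorm(3 * n), 3, n)
  y <- matrix(rnorm(3 * n), 3, n)
  fx <- signalMatrix(bandpassFilter(mk(x)))
  fy <- signalMatrix(bandpassFilter(mk(y)))
  fxy <- signalMatrix(bandpassFilter(mk(2 * x - 0.5 * y)))
  expect_equal(fxy, 2 * fx - 0.5 * fy, tolerance = 1e-8)
})

test_that("single-differential derivation drops pairs at the missing corner", {
  rec <- sineRecording(runif(64, 0.5, 1))
  d <- toSingleDifferential(rec)
  expect_equal(nChannels(d), 59L)
  expect_equal(gridGeometry(d)@nRows, 12L)
  expect_identical(recordingMode(d), "single_differential")
  expect_error(toSingleDifferential(d), "already")
})

test_that("differential derivation annihilates common-mode signals", {
  n <- 512L
  common <- sin(2 * pi * 60 * (seq_len(n) - 1L) / 1024)
  rec <- GridRecording(matrix(common, 64, n, byrow = TRUE))
  d <- toSingleDifferential(rec)
  expect_lt(max(abs(signalMatrix(d))), 1e-12)
})

test_that("a linear amplitude gradient along the fiber axis gives constant differentials", {
  g <- GridGeometry()
  pos <- defaultChannelMap(g)
  cPerRow <- 0.3
  sig <- matrix(rep(pos[, 1] * cPerRow, 16), 64, 16)
  rec <- GridRecording(sig, geometry = g)
  d <- toSingleDifferential(rec)
  expect_lt(max(abs(signalMatrix(d) + cPerRow)), 1e-12)
})

test_that("torque-threshold segmentation finds the trapezoid crossing", {
  cfg <- simulationConfig(durationS = 5, onsetS = 1, rampS = 0.5,
                          plateauS = 2.5, seed = 5)
  sim <- simulateRecording(cfg)
  seg <- segmentContraction(sim$recording, "torque", thresholdFrac = 0.1)
  # closed form: the ramp starting at 1.00 s crosses 10% of peak at 1.05 s
  tCross <- 1 + 0.1 * 0.5
  expect_lt(abs((seg@startSample - 1) / 1024 - tCross), 0.05)
  expect_identical(seg@method, "torque-threshold")

  recNoTorque <- GridRecording(signalMatrix(sim$recording),
                               geometry = gridGeometry(sim$recording))
  expect_error(segmentContraction(recNoTorque, "torque"), "no torque")
  zero <- GridRecording(signalMatrix(sim$recording),
                        geometry = gridGeometry(sim$recording),
                        torque = rep(0, 500))
  expect_error(segmentContraction(zero, "torque"), "no contraction")
})

test_that("envelope segmentation of a whole-record contraction spans nearly all of it", {
  n <- 2048L
  set.seed(8)
  sig <- matrix(rnorm(64 * n, sd = 0.1), 64, n)
  rec <- GridRecording(sig)
  seg <- segmentContraction(rec, "emg_envelope", thresholdFrac = 0.1)
  # stationary noise stays above 10% of peak except at smoothing edges
  expect_lt((seg@startSample - 1) / 1024, 0.15)
  expect_gt(seg@endSample / 1024, n / 1024 - 0.15)
})

test_that("windowed maps tile the segment and hold per-channel RMS", {
  rec <- sineRecording(rep(1, 64), durationS = 3)
  seg <- new("ContractionSegment", startSample = 1L, endSample = 3072L,
             method = "manual")
  maps <- windowedMaps(rec, seg, windowS = 1, overlapFrac = 0)
  expect_length(maps, 3L)
  # RMS of a unit sine is 1/sqrt(2)
  for (m in maps)
    expect_equal(unname(mapValues(m)[2, 1]), 1 / sqrt(2), tolerance = 1e-3)
  centers <- vapply(maps, function(m) mean(mapWindow(m)), numeric(1))
  expect_true(all(diff(centers) > 0))
  starts <- vapply(maps, function(m) mapWindow(m)[1], numeric(1))
  ends <- vapply(maps, function(m) mapWindow(m)[2], numeric(1))
  expect_equal(starts[-1], ends[-length(ends)])  # gap-free tiling
  expect_error(windowedMaps(rec, seg, windowS = 4), "longer than")
})

test_that("map count follows floor((duration - window)/step) + 1", {
  rec <- sineRecording(rep(1, 64), durationS = 3)
  seg <- new("ContractionSegment", startSample = 1L, endSample = 2867L,
             method = "manual")  # 2.8 s
  for (ov in c(0, 0.5)) {
    maps <- windowedMaps(rec, seg, windowS = 0.25, overlapFrac = ov)
    step <- 0.25 * (1 - ov)
    expect_length(maps, floor((2867 / 1024 - 0.25) / step) + 1)
  }
})

test_that("RMS maps scale linearly with the signals", {
  sim <- simulateRecording(quickConfig(seed = 2))
  rec <- sim$recording
  seg <- new("ContractionSegment", startSample = 1L,
             endSample = nSamples(rec), method = "manual")
  m1 <- midpointEpoch(rec, seg)
  rec3 <- GridRecording(3 * signalMatrix(rec), geometry = gridGeometry(rec))
  m3 <- midpointEpoch(rec3, seg)
  expect_equal(mapValues(m3), 3 * mapValues(m1))
})

test_that("midpoint epoch is centred on the segment midpoint", {
  rec <- sineRecording(rep(1, 64), durationS = 4)
  seg <- new("ContractionSegment", startSample = 1L, endSample = 4096L,
             method = "manual")
  m <- midpointEpoch(rec, seg, epochS = 0.25)
  expect_equal(mapWindow(m), c(1.875, 2.125), tolerance = 2 / 1024)
  # equals the windowed map positioned identically
  segEpoch <- new("ContractionSegment",
                  startSample = as.integer(mapWindow(m)[1] * 1024) + 1L,
                  endSample = as.integer(mapWindow(m)[2] * 1024),
                  method = "manual")
  mw <- windowedMaps(rec, segEpoch, windowS = 0.25)[[1]]
  expect_equal(mapValues(mw), mapValues(m))
  expect_error(midpointEpoch(rec, seg, epochS = 10), "longer than")
})

test_that("the midpoint epoch of a stationary process tracks the full-segment RMS", {
  errs <- vapply(1:5, function(s) {
    sim <- simulateRecording(quickConfig(seed = 100 + s, onsetS = 0,
                                         rampS = 0.05, plateauS = 1.9))
    rec <- sim$recording
    seg <- new("ContractionSegment", startSample = 103L,
               endSample = nSamples(rec) - 102L, method = "manual")
    epoch <- meanRMS(midpointEpoch(rec, seg))
    segLenS <- (seg@endSample - seg@startSample + 1) / samplingRate(rec)
    whole <- meanRMS(windowedMaps(rec, seg, windowS = segLenS)[[1]])
    abs(epoch - whole) / whole
  }, numeric(1))
  expect_lt(mean(errs), 0.15)
})
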