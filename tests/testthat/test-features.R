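# brute-force feature oracles by naive summation, independent of the
# package implementations
naiveEntropy <- function(v) {
  q <- v^2 / sum(v^2)
  s <- 0
  for (qi in q) if (qi > 0) s <- s - qi * log2(qi)
  s
}
naiveCoV <- function(v) {
  m <- sum(v) / length(v)
  ss <- 0
  for (vi in v) ss <- ss + (vi - m)^2
  100 * sqrt(ss / (length(v) - 1)) / m
}

test_that("modified entropy hits its analytic extremes", {
  expect_equal(modifiedEntropy(map59(rep(0.5, 59))), log2(59))
  expect_equal(log2(59), 5.8826, tolerance = 1e-4)
  expect_equal(modifiedEntropy(map59(c(1, rep(0, 58)))), 0)
  expect_equal(modifiedEntropy(map59(c(0.3, 0.3, rep(0, 57)))), 1.0)
  expect_error(modifiedEntropy(map59(rep(0, 59))), "all-zero")
})

test_that("entropy is bounded by log2(N) and scale-invariant", {
  set.seed(21)
  for (i in 1:20) {
    v <- rexp(59)
    m <- map59(v)
    e <- modifiedEntropy(m)
    expect_gte(e, 0)
    expect_lte(e, log2(59) + 1e-12)
    expect_equal(modifiedEntropy(map59(37.1 * v)), e, tolerance = 1e-12)
    expect_equal(e, naiveEntropy(v), tolerance = 1e-10)
  }
})

test_that("intensity is the common log of the map mean", {
  expect_equal(mapIntensity(map59(rep(0.1, 59))), -1.0)
  expect_equal(mapIntensity(map59(rep(1.0, 59))), 0.0)
  set.seed(4)
  v <- rexp(59, rate = 10)
  expect_equal(mapIntensity(map59(10 * v)), mapIntensity(map59(v)) + 1,
               tolerance = 1e-12)
  expect_equal(mapIntensity(map59(v)), log10(meanRMS(map59(v))),
               tolerance = 1e-12)
  expect_error(mapIntensity(map59(rep(0, 59))), "undefined")
})

test_that("differential intensity follows the same log-of-mean convention", {
  expect_equal(differentialIntensity(map59(rep(0.1, 59))), -1.0)
  set.seed(5)
  v <- rexp(59, rate = 10)
  expect_equal(differentialIntensity(map59(10 * v)),
               differentialIntensity(map59(v)) + 1, tolerance = 1e-12)
  mono <- activationMapFromMatrix(matrix(0.1, 13, 5))
  expect_error(differentialIntensity(mono), "single-differential")
  expect_error(differentialIntensity(map59(rep(0, 59))),
               "no differential activity")
})

test_that("CoV matches direct arithmetic and is scale-invariant", {
  expect_equal(spatialCoV(map59(rep(0.2, 59))), 0)
  v <- c(rep(1.0, 29), rep(2.0, 30))
  expect_equal(spatialCoV(map59(v)), naiveCoV(v), tolerance = 1e-10)
  set.seed(6)
  w <- rexp(59)
  expect_equal(spatialCoV(map59(2.5 * w)), spatialCoV(map59(w)),
               tolerance = 1e-10)
})

test_that("mean RMS averages valid positions only", {
  expect_equal(meanRMS(map59(rep(0.07, 59))), 0.07)
  m <- matrix(1, 13, 5); m[1, 1] <- NA; m[13, 5] <- 100
  map <- activationMapFromMatrix(m)
  expect_equal(meanRMS(map), (63 + 100) / 64)
})

test_that("median frequency resolves pure and composite tones", {
  rec <- sineRecording(rep(1, 64), freqHz = 80, durationS = 1)
  expect_lt(abs(medianFrequency(rec) - 80), 1.01)  # one 1 Hz bin
  # equal-power tones at 50 and 150 Hz: the smallest frequency at which
  # cumulative power reaches half the total is the lower tone
  n <- 1024L; t <- (seq_len(n) - 1L) / 1024
  x <- sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t)
  rec2 <- GridRecording(matrix(x, 64, n, byrow = TRUE))
  expect_lt(abs(medianFrequency(rec2) - 50), 1.01)
})

test_that("median frequency of flat band-limited noise sits at the band midpoint", {
  fms <- vapply(1:8, function(s) {
    sim <- simulateRecording(quickConfig(seed = 300 + s))
    rec <- sim$recording
    seg <- segmentContraction(rec, "torque")
    medianFrequency(rec, seg)
  }, numeric(1))
  expect_equal(mean(fms), 210, tolerance = 5 / 210)
  expect_true(all(fms >= 20 & fms <= 400))
})

test_that("silent channels are excluded and an all-silent epoch errors", {
  amps <- rep(1, 64); amps[5] <- 0
  rec <- sineRecording(amps, freqHz = 80)
  expect_lt(abs(medianFrequency(rec) - 80), 1.01)
  zero <- GridRecording(matrix(0, 64, 512))
  expect_error(medianFrequency(zero), "silent")
  expect_error(medianFrequency(rec, new("ContractionSegment",
                                        startSample = 1L, endSample = 130L,
                                        method = "manual"), epochS = 0.05),
               "128 samples")
})

test_that("featureSet composes the six features coherently", {
  # near-uniform spatial envelope: entropy near its maximum, CoV small
  sim <- simulateRecording(quickConfig(seed = 31, sigmaRows = 100,
                                       sigmaCols = 100))
  fs <- featureSet(sim$recording)
  expect_gt(fs$entropy, 0.98 * log2(59))
  expect_lt(fs$cov, 25)
  expect_equal(fs$intensity, log10(fs$mean_rms), tolerance = 1e-12)

  # localised source: strictly lower entropy, higher CoV
  simLoc <- simulateRecording(quickConfig(seed = 31, sigmaRows = 1.2,
                                          sigmaCols = 0.8))
  fsLoc <- featureSet(simLoc$recording)
  expect_lt(fsLoc$entropy, fs$entropy)
  expect_gt(fsLoc$cov, fs$cov)
  # differential and monopolar amplitude features are distinct measurements
  expect_false(isTRUE(all.equal(fs$differential_intensity, fs$intensity)))
})
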