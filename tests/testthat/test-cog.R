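test_that("barycentre of analytic maps matches closed forms", {
  uni <- activationMapFromMatrix(matrix(1, 13, 5))
  expect_equal(cogPoint(uni), c(x = 7, y = 3))

  delta <- matrix(0, 13, 5); delta[2, 4] <- 0.3
  expect_equal(cogPoint(activationMapFromMatrix(delta)), c(x = 2, y = 4))

  two <- matrix(0, 13, 5); two[1, 1] <- 1; two[13, 5] <- 1
  expect_equal(cogPoint(activationMapFromMatrix(two)), c(x = 7, y = 3))

  expect_error(cogPoint(activationMapFromMatrix(matrix(0, 13, 5))),
               "all-zero")
})

test_that("barycentre is scale-invariant and mask-aware", {
  set.seed(12)
  m <- matrix(rexp(65), 13, 5)
  map <- activationMapFromMatrix(m)
  expect_equal(cogPoint(activationMapFromMatrix(9.7 * m)), cogPoint(map),
               tolerance = 1e-12)
  # masking a heavy corner moves the barycentre
  m2 <- m; m2[13, 5] <- NA
  expect_false(isTRUE(all.equal(cogPoint(activationMapFromMatrix(m2)),
                                cogPoint(map))))
})

mkMaps <- function(totals, at = 2) {
  lapply(seq_along(totals), function(i) {
    m <- matrix(totals[i] / 65, 13, 5)
    m[at, at] <- m[at, at] * 2
    activationMapFromMatrix(m, window = c(i - 1, i))
  })
}

test_that("reference rules select the intended window", {
  maps <- mkMaps(c(1, 2, 5, 2, 1))
  ref <- cogReference(maps, "peak_intensity")
  expect_equal(attr(ref, "window"), 3L)
  ref <- cogReference(maps, "midpoint")
  expect_equal(attr(ref, "window"), 3L)
  # trapezoid torque peaking in the fourth second
  torque <- c(seq(0, 100, length.out = 350), seq(100, 0, length.out = 150))
  ref <- cogReference(maps, "peak_torque", torque = torque, torqueFsHz = 100)
  expect_equal(attr(ref, "window"), 4L)
  expect_error(cogReference(maps, "peak_torque"), "torque")
  # single-map sequence: all rules agree
  one <- maps[3]
  expect_equal(cogReference(one, "peak_intensity"),
               cogReference(one, "midpoint"))
})

test_that("trajectory summaries report mean, variance and min-max range per axis", {
  m1 <- matrix(0, 13, 5); m1[4, 3] <- 1
  m2 <- matrix(0, 13, 5); m2[10, 3] <- 1
  maps <- list(activationMapFromMatrix(m1, window = c(0, 1)),
               activationMapFromMatrix(m2, window = c(1, 2)))
  traj <- cogTrajectory(maps)
  s <- trajSummary(traj)
  expect_equal(s$cogx_mean, 7)
  expect_equal(s$cogx_range, 6)
  expect_equal(s$cogy_range, 0)
  expect_equal(s$cogx_sd, sqrt(s$cogx_var))
  expect_true(s$cogx_mean >= min(trajX(traj)) &&
              s$cogx_mean <= max(trajX(traj)))

  # two identical maps: variance exactly 0
  traj0 <- cogTrajectory(list(activationMapFromMatrix(m1, window = c(0, 1)),
                              activationMapFromMatrix(m1, window = c(1, 2))))
  expect_identical(trajSummary(traj0)$cogx_var, 0)
})

test_that("all-zero windows are skipped with a warning", {
  m1 <- matrix(0, 13, 5); m1[4, 3] <- 1
  z <- matrix(0, 13, 5)
  maps <- list(activationMapFromMatrix(m1, window = c(0, 1)),
               activationMapFromMatrix(z, window = c(1, 2)),
               activationMapFromMatrix(m1, window = c(2, 3)))
  expect_warning(traj <- cogTrajectory(maps), "skipped")
  expect_length(trajTimes(traj), 2L)
  zz <- list(activationMapFromMatrix(z, window = c(0, 1)),
             activationMapFromMatrix(z, window = c(1, 2)))
  expect_error(suppressWarnings(cogTrajectory(zz)), "all-zero")
})

test_that("for a single-window contraction the trajectory mean equals the point CoG", {
  sim <- simulateRecording(quickConfig(seed = 9))
  rec <- sim$recording
  seg <- segmentContraction(rec, "torque")
  segLenS <- (seg@endSample - seg@startSample + 1) / samplingRate(rec)
  maps <- windowedMaps(rec, seg, windowS = segLenS / 2)
  traj <- cogTrajectory(maps)
  pt <- cogPoint(maps[[1]])
  expect_identical(trajX(traj)[1], unname(pt["x"]))
})

test_that("method agreement recovers perfect and inverted relations", {
  pts <- data.frame(x = c(5, 6, 7, 8), y = c(2.8, 3, 3.2, 3.1))
  out <- compareCoGMethods(pts, pts)
  expect_equal(out$r, c(1, 1))
  expect_equal(out$r2, c(1, 1))
  neg <- data.frame(x = -pts$x, y = -pts$y)
  out <- compareCoGMethods(pts, neg)
  expect_equal(out$r, c(-1, -1))
  # zero variance: undefined, reported as NA
  const <- data.frame(x = rep(7, 4), y = pts$y)
  out <- compareCoGMethods(const, pts)
  expect_true(is.na(out$r[out$axis == "x"]))
  expect_error(compareCoGMethods(pts[1:2, ], pts[1:2, ]), "at least 3")
})

test_that("barycentre recovery is translation-equivariant in the envelope", {
  # compact source so grid-edge truncation of the envelope stays negligible
  cogAt <- function(cx, seed) {
    sim <- simulateRecording(quickConfig(
      seed = seed, centerPath = cbind(c(0, 2), cx, 3),
      sigmaRows = 1.5, sigmaCols = 1))
    rec <- sim$recording
    seg <- segmentContraction(rec, "torque")
    cogPoint(midpointEpoch(rec, seg))
  }
  shifts <- vapply(1:5, function(s)
    cogAt(8, 40 + s)[["x"]] - cogAt(7, 40 + s)[["x"]], numeric(1))
  expect_equal(mean(shifts), 1, tolerance = 0.15)
})
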