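test_that("autocorrelation period matches a pure tone", {
  t <- 0:199
  track <- cbind(cos(2 * pi * t / 20), sin(2 * pi * t / 20))
  expect_equal(estimatePeriod(track, dt = 1), 20, tolerance = 0.01)
  expect_equal(estimatePeriod(track, dt = 0.002), 20 * 0.002, tolerance = 1e-4)
})

test_that("the estimator returns the fundamental, not a harmonic", {
  t <- 0:299
  track <- cbind(cos(2 * pi * t / 30) + 0.3 * cos(4 * pi * t / 30), 0 * t)
  T <- estimatePeriod(track, dt = 1)
  expect_equal(T, 30, tolerance = 0.5)
  expect_gt(abs(T - 15), 10)  # must not lock onto the half-period harmonic
})

test_that("aperiodic trajectories are rejected", {
  expect_error(estimatePeriod(matrix(1, 50, 2), dt = 1), "constant trajectory")
  set.seed(42)
  drift <- cbind(seq(0, 10, length.out = 100), seq(0, -3, length.out = 100))
  expect_error(estimatePeriod(drift, dt = 1), "no autocorrelation peak")
})

test_that("sperm-frame transform is a rigid-motion invariant", {
  set.seed(7)
  cfg <- simConfig(nSwimmers = 1, pointsPerFrame = 40, beatsRecorded = 2,
                   framesPerBeat = 10, noiseSD = 0)
  cap <- simulateSwimmer(cfg)$capture
  ref <- toSpermFrame(cap)
  # base at origin in every frame
  bases <- t(vapply(ref@frames, function(f) f[1, ], numeric(2)))
  expect_lt(max(abs(bases)), 1e-9)

  # rigidly moved copy maps to the same body frame
  R <- matrix(c(cos(1.1), sin(1.1), -sin(1.1), cos(1.1)), 2, 2)
  moved <- RawCapture(lapply(cap@frames, function(f)
    sweep(f %*% R, 2, c(-12.3, 4.5), `+`)), cap@timestamps)
  ref2 <- toSpermFrame(moved)
  dev <- max(mapply(function(a, b) max(abs(a - b)), ref@frames, ref2@frames))
  expect_lt(dev, 1e-9)

  # already body-fixed input is (numerically) a fixed point
  ref3 <- toSpermFrame(ref)
  dev <- max(mapply(function(a, b) max(abs(a - b)), ref@frames, ref3@frames))
  expect_lt(dev, 1e-9)
})

test_that("beat-start search minimizes midpoint recurrence distance", {
  # exactly periodic record: zero distance everywhere, smallest t wins
  nS <- 51
  tvec <- seq(0, 3, by = 1 / 30)   # one period is a whole number of frames
  s <- seq(0, 1, length.out = nS)
  X <- outer(s, tvec, function(s, t) s)
  Y <- outer(s, tvec, function(s, t) 0.1 * sin(2 * pi * (t - s)))
  expect_equal(findBeatStart(X, Y, tvec), 0)

  # transient before t = 0.9: the recurrence distance is only small later
  Yt <- Y + outer(rep(1, nS), pmax(0, 0.9 - tvec)) * 0.5
  expect_gte(findBeatStart(X, Yt, tvec), 0.85)

  expect_error(findBeatStart(X[, 1:20], Y[, 1:20], tvec[1:20] / 4),
               "less than one period")
})

test_that("phase alignment is an exact circular shift with a fixed maximum convention", {
  beat <- makeBeat(function(s, t) 0.5 * (0.5 + s) * sin(2 * pi * (t - s)),
                   nS = 101, nT = 50)
  al <- alignPhase(beat)
  mid <- ceiling(101 / 2)
  expect_equal(which.max(yCoords(al)[mid, ]), 1L)
  # aligning twice is the identity
  expect_identical(xCoords(alignPhase(al)), xCoords(al))

  # a beat shifted by 37 timepoints aligns back to the same waveform
  idx <- c(38:50, 1:37)
  shifted <- beat
  shifted@waveform <- CartesianWaveform(xCoords(beat)[, idx], yCoords(beat)[, idx])
  expect_equal(xCoords(alignPhase(shifted)), xCoords(alignPhase(beat)),
               tolerance = 1e-12)
  expect_equal(yCoords(alignPhase(shifted)), yCoords(alignPhase(beat)),
               tolerance = 1e-12)
})

test_that("pipeline recovers simulated length and period on the exact grid", {
  set.seed(11)
  cfg <- simConfig(nSwimmers = 1, noiseSD = 0.01, pointsPerFrame = 101)
  sw <- simulateSwimmer(cfg, swimmerID = "p1")
  beat <- preprocessBeat(sw$capture, nS = 1000, nT = 100)
  expect_identical(dim(xCoords(beat)), c(1000L, 100L))
  expect_lt(abs(flagellumLength(beat) - sw$truth$L) / sw$truth$L, 0.01)
  frameInt <- cfg$meanPeriod / cfg$framesPerBeat
  expect_lt(abs(beatPeriod(beat) - sw$truth$T), frameInt)
  # normalized output: equal chords summing to one
  ch <- sqrt(diff(xCoords(beat))^2 + diff(yCoords(beat))^2)
  expect_lt(max(abs(ch - 1 / 999)) * 999, 0.01)
  expect_lt(max(abs(colSums(ch) - 1)), 1e-9)
})

test_that("pipeline is invariant under rigid motion and time rescaling", {
  set.seed(13)
  cfg <- simConfig(nSwimmers = 1, noiseSD = 0, pointsPerFrame = 80)
  cap <- simulateSwimmer(cfg, swimmerID = "inv")$capture
  b0 <- preprocessBeat(cap, nS = 300, nT = 50)

  R <- matrix(c(cos(0.7), sin(0.7), -sin(0.7), cos(0.7)), 2, 2)
  capR <- RawCapture(lapply(cap@frames, function(f)
    sweep(f %*% R, 2, c(5, -8), `+`)), cap@timestamps, "inv")
  bR <- preprocessBeat(capR, nS = 300, nT = 50)
  expect_lt(max(abs(xCoords(bR) - xCoords(b0))), 1e-3)
  expect_lt(max(abs(yCoords(bR) - yCoords(b0))), 1e-3)

  # doubling all timestamps (same motion, halved frame rate) rescales T only
  cap2 <- RawCapture(cap@frames, cap@timestamps * 2, "inv")
  b2 <- preprocessBeat(cap2, nS = 300, nT = 50)
  expect_equal(beatPeriod(b2), 2 * beatPeriod(b0), tolerance = 1e-6)
  expect_lt(max(abs(xCoords(b2) - xCoords(b0))), 1e-3)
  expect_lt(max(abs(yCoords(b2) - yCoords(b0))), 1e-3)
})

test_that("records that are too short are refused", {
  set.seed(17)
  cfg <- simConfig(nSwimmers = 1, beatsRecorded = 2, noiseSD = 0,
                   pointsPerFrame = 40)
  cap <- simulateSwimmer(cfg)$capture   # spans just under two periods
  expect_error(preprocessBeat(cap, nS = 100, nT = 20), "insufficient data")
})
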