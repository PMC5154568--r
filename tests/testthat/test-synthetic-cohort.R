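# Synthetic cohort generator: subject age maps, analytic waveform,
# series/stack generation, cohort structure.

test_that("subject generation is deterministic and respects its bounds", {
  p1 <- simulateSubject(40, "female", seed = 11)
  p2 <- simulateSubject(40, "female", seed = 11)
  expect_identical(p1, p2)
  p3 <- simulateSubject(40, "female", seed = 12)
  expect_false(identical(p1@diastolicDecayTau, p3@diastolicDecayTau))
  expect_error(simulateSubject(17, "female", seed = 1), "\\[18, 80\\]")
  expect_error(simulateSubject(81, "male", seed = 1), "\\[18, 80\\]")
  expect_true(validObject(p1))
  # generator must not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(1)
  set.seed(99); invisible(simulateSubject(30, "male", seed = 5)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("diastolic decay shortens and rise fraction narrows with age in expectation", {
  seeds <- 1:120
  young <- vapply(seeds, function(s)
    simulateSubject(25, "female", seed = s)@diastolicDecayTau, numeric(1))
  old <- vapply(seeds, function(s)
    simulateSubject(75, "female", seed = s)@diastolicDecayTau, numeric(1))
  expect_gt(mean(young), mean(old))
  riseY <- vapply(seeds, function(s)
    simulateSubject(25, "female", seed = s)@systolicRiseFraction, numeric(1))
  riseO <- vapply(seeds, function(s)
    simulateSubject(75, "female", seed = s)@systolicRiseFraction, numeric(1))
  expect_gte(mean(riseY), mean(riseO))
})

test_that("male profiles carry higher systolic blood pressure on average", {
  seeds <- 1:120
  m <- vapply(seeds, function(s) simulateSubject(50, "male", seed = s)@sbp,
              numeric(1))
  f <- vapply(seeds, function(s) simulateSubject(50, "female", seed = s)@sbp,
              numeric(1))
  expect_gt(mean(m), mean(f))
})

test_that("the analytic waveform is periodic, continuous and single-peaked", {
  p <- simulateSubject(45, "male", seed = 3)
  P <- 60 / p@heartRate
  t <- seq(0, P, length.out = 200)
  expect_equal(mbrWaveform(p, t), mbrWaveform(p, t + 3 * P), tolerance = 1e-12)
  # continuity across the cycle wrap
  expect_lt(abs(mbrWaveform(p, P - 1e-7) - mbrWaveform(p, P + 1e-7)), 1e-3)
  # single maximum at the systolic rise fraction (dense grid argmax)
  tg <- (seq_len(20000) - 1) / 20000 * P
  v <- mbrWaveform(p, tg)
  expect_equal(tg[which.max(v)] / P, p@systolicRiseFraction, tolerance = 1e-3)
  expect_equal(sum(diff(sign(diff(v))) < 0), 1)  # exactly one interior peak
  expect_error(mbrWaveform(p, -1), ">= 0")
})

test_that("zero pulse amplitude degenerates to a constant baseline", {
  p <- simulateSubject(45, "male", seed = 3)
  p@pulseAmplitude <- 0
  expect_equal(mbrWaveform(p, seq(0, 3, by = 0.05)),
               rep(p@mbrBaseline, 61))
})

test_that("series generation samples the analytic curve exactly at zero noise", {
  p <- simulateSubject(30, "female", seed = 8)
  s <- generateMbrSeries(p, nFrames = 118, frameRate = 30, seed = 1,
                         phaseOffset = 0, noiseSd = 0)
  expect_equal(mbrValues(s),
               mbrWaveform(p, (0:117) / 30), tolerance = 1e-12)
  s2 <- generateMbrSeries(p, seed = 21)
  s3 <- generateMbrSeries(p, seed = 21)
  expect_identical(mbrValues(s2), mbrValues(s3))
  # too short to hold two cardiac cycles
  expect_error(generateMbrSeries(p, nFrames = 30, frameRate = 30),
               "2 cardiac cycles")
})

test_that("measurement noise has the expected mean absolute deviation", {
  p <- simulateSubject(30, "female", seed = 8)
  sigma <- 0.5
  devs <- unlist(lapply(1:40, function(s) {
    ser <- generateMbrSeries(p, seed = s, phaseOffset = 0, noiseSd = sigma)
    abs(mbrValues(ser) - mbrWaveform(p, (0:117) / 30))
  }))
  expect_equal(mean(devs), sigma * sqrt(2 / pi), tolerance = 0.03)
})

test_that("flow-map stacks realize the scene's vessel/tissue contrast", {
  scene <- makeScene(height = 60, width = 80, semiAxes = c(25, 18),
                     tissueFlowScale = 10, vesselFlowScale = 20, seed = 2)
  p <- simulateSubject(40, "male", seed = 4)
  st <- generateFlowMapStack(p, scene, nFrames = 64, frameRate = 30,
                             seed = 1, noiseSd = 0)
  tm <- apply(st@frames, c(1, 2), mean)
  # time-mean vessel / tissue pixel ratio equals the scale ratio (2)
  expect_equal(mean(tm[scene@vesselMask]) / mean(tm[!scene@vesselMask]), 2,
               tolerance = 1e-6)
  # perfectly separable by a single threshold at zero noise
  thr <- (max(tm[!scene@vesselMask]) + min(tm[scene@vesselMask])) / 2
  expect_identical(tm > thr, scene@vesselMask)
  st2 <- generateFlowMapStack(p, scene, nFrames = 64, seed = 9, noiseSd = 1)
  st3 <- generateFlowMapStack(p, scene, nFrames = 64, seed = 9, noiseSd = 1)
  expect_identical(st2@frames, st3@frames)
})

test_that("scene construction rejects an ellipse leaving the frame", {
  expect_error(makeScene(height = 40, width = 40, semiAxes = c(30, 10)),
               "inside the frame")
})

test_that("the cohort has the study's group structure and schema", {
  coh <- simulateCohort(nPerCell = 10, repeats = 3, seed = 2)
  tbl <- cohortTable(coh)
  expect_equal(length(unique(tbl$subject_id)), 80)
  expect_equal(sum(tbl$condition == "undilated"), 240)
  expect_equal(sum(tbl$condition == "dilated"), 240)
  subj <- unique(tbl[c("subject_id", "age", "sex")])
  expect_equal(as.vector(table(subj$sex)), c(40L, 40L))
  brk <- cut(subj$age, c(17, 34, 49, 64, 80))
  expect_equal(as.vector(table(brk)), rep(20L, 4))
  expect_true(all(is.na(tbl$MA[!tbl$scan_success])))
  expect_true(all(!is.na(tbl$MA[tbl$scan_success])))
  expect_error(simulateCohort(nPerCell = 2, repeats = 1, seed = 1),
               "repeats")
})

test_that("the cohort generator is a pure function of its seed", {
  a <- cohortTable(simulateCohort(nPerCell = 2, repeats = 2, seed = 7))
  b <- cohortTable(simulateCohort(nPerCell = 2, repeats = 2, seed = 7))
  expect_identical(a, b)
})

test_that("MV exceeds MA exceeds MT in successful scans", {
  tbl <- cohortTable(simulateCohort(nPerCell = 3, repeats = 2, seed = 13))
  ok <- tbl[tbl$scan_success & tbl$condition == "undilated", ]
  expect_true(all(ok$MV > ok$MA & ok$MA > ok$MT))
})
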