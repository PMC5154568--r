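# Cycle detection, composite-cycle construction, and the eight
# pulse-waveform indices with their invariants.

test_that("cycle detection recovers trough-to-trough cycles of a clean series", {
  p <- simulateSubject(40, "female", seed = 1)
  p@heartRate <- 60
  s <- generateMbrSeries(p, nFrames = 118, frameRate = 30, seed = 1,
                         phaseOffset = 0, noiseSd = 0)
  seg <- detectCycles(s)
  expect_gte(nCycles(seg), 3)
  expect_true(all(abs(diff(cycleBoundaries(seg)) - 30) <= 1))
})

test_that("a constant series has no detectable cardiac cycle", {
  s <- MbrSeries(rep(5, 100), frameRate = 30)
  expect_error(detectCycles(s), "no cardiac cycle detected")
})

test_that("detected cycle duration tracks the true heart rate under noise", {
  durations <- vapply(1:25, function(sd) {
    p <- simulateSubject(50, "male", seed = sd)
    s <- generateMbrSeries(p, seed = sd,
                           noiseSd = 0.05 * p@pulseAmplitude)
    seg <- detectCycles(s)
    mean(diff(cycleBoundaries(seg))) / frameRate(s) * p@heartRate / 60
  }, numeric(1))
  # normalized duration (true period = 1): 5% accuracy on average, with
  # single-scan outliers bounded by trough jitter on the flat diastolic tail
  expect_lt(mean(abs(durations - 1)), 0.05)
  expect_lt(max(abs(durations - 1)), 0.10)
})

test_that("composite cycle reduces to identity for a single clean cycle", {
  v <- pulseLikeCycle(30)
  s <- MbrSeries(c(v, v, v, v[1]), frameRate = 30)
  seg <- detectCycles(s, smoothWidth = 1)
  cyc <- compositeCycle(s, seg, nPhaseBins = 30)
  # identical cycles: composite equals any one of them
  expect_equal(mbrValues(cyc), v, tolerance = 1e-10)
  expect_equal(cycleDuration(cyc), 1, tolerance = 1e-12)
  expect_error(compositeCycle(s, seg, nPhaseBins = 4), ">= 8")
})

test_that("averaging cycles reduces noise relative to single cycles", {
  v <- pulseLikeCycle(30)
  wins <- vapply(1:100, function(sd) {
    set.seed(sd)
    series <- c(rep(v, 4), v[1]) + rnorm(121, 0, 0.4)
    s <- MbrSeries(pmax(series, 0), frameRate = 30)
    seg <- new("CycleSegmentation", boundaries = c(1L, 31L, 61L, 91L, 121L),
               frameRate = 30)
    comp <- mbrValues(compositeCycle(s, seg, 30))
    singles <- vapply(1:4, function(j) {
      sj <- new("CycleSegmentation", boundaries = seg@boundaries[j:(j + 1)],
                frameRate = 30)
      sqrt(mean((mbrValues(compositeCycle(s, sj, 30)) - v)^2))
    }, numeric(1))
    sqrt(mean((comp - v)^2)) < median(singles)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("blowout time matches constructed half-width fractions", {
  n <- 30
  tri <- 1 - 2 * abs((seq_len(n) - 1) / n - 0.5)
  expect_equal(blowoutTime(tri), 50)
  sq <- rep(c(1, 0), c(9, 21))  # 30% duty square wave
  expect_equal(blowoutTime(sq), oracleBot(sq))
  expect_equal(blowoutTime(sq), 30)
  expect_warning(bt <- blowoutTime(rep(2, 12)), "flat")
  expect_equal(bt, 100)
  for (sd in 1:20) {
    set.seed(sd)
    v <- abs(rnorm(24, 10, 3))
    b <- blowoutTime(v)
    expect_gte(b, 0); expect_lte(b, 100)
    expect_equal(b, oracleBot(v))
  }
})

test_that("blowout score follows its max/min/mean formula and clips", {
  v <- pulseLikeCycle(32)
  expect_equal(blowoutScore(v), oracleBos(v))
  # max 16, min 10, mean 12.8 -> 100 * (1 - 6 / 25.6)
  cyc <- c(16, 10, rep((12.8 * 16 - 26) / 14, 14))
  expect_equal(mean(cyc), 12.8)
  expect_equal(blowoutScore(cyc), 100 * (1 - 6 / 25.6), tolerance = 1e-9)
  expect_equal(blowoutScore(rep(7, 10)), 100)  # flat: perfect constancy
  expect_error(blowoutScore(rep(0, 10)), "mean")
})

test_that("skew is zero for symmetric cycles, positive for early peaks, odd under mirroring", {
  n <- 30
  tri <- 1 - 2 * abs((seq_len(n) - 0.5) / n - 0.5)
  expect_equal(waveformSkew(tri), 0, tolerance = 1e-10)
  saw <- pulseLikeCycle(30, rise = 0.15, tau = 0.35)  # fast rise, slow fall
  expect_gt(waveformSkew(saw), 0)
  expect_equal(waveformSkew(rev(saw)), -waveformSkew(saw), tolerance = 1e-10)
  expect_equal(waveformSkew(saw), oracleSkew(saw), tolerance = 1e-12)
  # steeper post-peak decline increases skew
  expect_gt(waveformSkew(pulseLikeCycle(30, tau = 0.2)),
            waveformSkew(pulseLikeCycle(30, tau = 0.5)))
  expect_error(waveformSkew(rep(3, 10)), "skew undefined")
})

test_that("acceleration time index is the relative time to peak", {
  v <- c(rep(0, 10), 1, rep(0, 29))
  expect_equal(accelerationTimeIndex(v), 25)
  expect_equal(accelerationTimeIndex(c(5, 1, 2, 3)), 0)
  # ties resolve to the first occurrence
  expect_equal(accelerationTimeIndex(c(0, 1, 1, 0)), 25)
  p <- simulateSubject(40, "female", seed = 2)
  p@systolicRiseFraction <- 0.3
  v <- analyticCycle(p, 30)
  expect_equal(accelerationTimeIndex(v), 30, tolerance = 100 / 30)
})

test_that("rising and falling rates are symmetric for a trapezoid and monotone in tau", {
  trap <- c(rep(0, 5), 0.25, 0.5, 0.75, rep(1, 5), 0.75, 0.5, 0.25,
            rep(0, 4)) + 1
  expect_equal(risingRate(trap), fallingRate(trap))
  p <- simulateSubject(40, "female", seed = 2)
  pFast <- p; pFast@diastolicDecayTau <- p@diastolicDecayTau / 2
  expect_gt(fallingRate(analyticCycle(pFast, 30)),
            fallingRate(analyticCycle(p, 30)))
  v <- analyticCycle(p, 30)
  expect_equal(unname(oracleRates(v)["rr"]), risingRate(v))
  expect_equal(unname(oracleRates(v)["fr"]), fallingRate(v))
  expect_error(risingRate(rep(1, 10)), "flat")
})

test_that("flow acceleration index equals the brute-force max adjacent increment", {
  expect_equal(flowAccelerationIndex(c(1, 2, 4, 3)), 2)
  expect_equal(flowAccelerationIndex(rep(3, 10)), 0)
  for (sd in 1:25) {
    set.seed(sd)
    v <- abs(rnorm(20, 10, 4))
    expect_equal(flowAccelerationIndex(v), oracleFaiBrute(v))
    expect_gte(flowAccelerationIndex(v), 0)
  }
})

test_that("resistivity index spans its [0, 1] range as constructed", {
  expect_equal(resistivityIndex(c(10, 6, 8, 9)), 0.4)
  expect_equal(resistivityIndex(rep(4, 8)), 0)
  expect_equal(resistivityIndex(c(0, 1, 0.5, 0)), 1)
  expect_error(resistivityIndex(rep(0, 8)), "maximum")
})

test_that("indices are scale-invariant except meanMbr and FAI which scale linearly", {
  v <- pulseLikeCycle(30)
  c3 <- v * 3
  expect_equal(blowoutTime(c3), blowoutTime(v))
  expect_equal(blowoutScore(c3), blowoutScore(v))
  expect_equal(waveformSkew(c3), waveformSkew(v))
  expect_equal(accelerationTimeIndex(c3), accelerationTimeIndex(v))
  expect_equal(risingRate(c3), risingRate(v))
  expect_equal(fallingRate(c3), fallingRate(v))
  expect_equal(resistivityIndex(c3), resistivityIndex(v))
  expect_equal(flowAccelerationIndex(c3), 3 * flowAccelerationIndex(v))
  expect_equal(mean(c3), 3 * mean(v))
})

test_that("time reversal swaps the limbs, negates skew and mirrors the peak time", {
  for (sd in 1:10) {
    p <- simulateSubject(20 + 6 * sd, "male", seed = sd)
    v <- analyticCycle(p, 30)
    r <- rev(v)
    expect_equal(risingRate(r), fallingRate(v), tolerance = 1e-9)
    expect_equal(fallingRate(r), risingRate(v), tolerance = 1e-9)
    expect_equal(waveformSkew(r), -waveformSkew(v), tolerance = 1e-9)
    expect_equal(accelerationTimeIndex(r), 100 - accelerationTimeIndex(v),
                 tolerance = 100 / 30 + 1e-9)
    expect_equal(blowoutTime(r), blowoutTime(v))
    expect_equal(blowoutScore(r), blowoutScore(v))
    expect_equal(resistivityIndex(r), resistivityIndex(v))
    # reversal turns the max increment into the max decrement
    expect_equal(flowAccelerationIndex(r), max(-diff(c(v, v[1]))))
  }
})

test_that("index bounds hold on every analysed synthetic scan", {
  for (sd in 1:15) {
    p <- simulateSubject(18 + 4 * sd, if (sd %% 2) "male" else "female",
                         seed = sd)
    s <- generateMbrSeries(p, seed = sd)
    wi <- waveformProfile(s)
    df <- as.data.frame(wi)
    expect_true(df$BOT >= 0 && df$BOT <= 100)
    expect_true(df$BOS >= 0 && df$BOS <= 100)
    expect_true(df$ATI >= 0 && df$ATI < 100)
    expect_true(df$RI >= 0 && df$RI <= 1)
    expect_gte(df$FAI, 0)
    expect_gt(df$meanMbr, 0)
  }
})

test_that("the blowout-score / resistivity-index identity is exact", {
  for (sd in 1:1000) {
    set.seed(sd)
    v <- abs(rnorm(16, 10, 3)) + 0.5
    bos <- suppressWarnings(blowoutScore(v))
    if (bos <= 0 || bos >= 100) next  # clipped cycles leave the identity
    expect_equal(bos,
                 100 * (1 - resistivityIndex(v) * max(v) / (2 * mean(v))),
                 tolerance = 1e-12)
  }
})

test_that("waveformProfile matches the analytic oracle on clean scans", {
  ages <- c(30, 50, 70)
  for (sd in c(1, 5, 9)) {
    p <- simulateSubject(ages[(sd + 3) %/% 4], "female", seed = sd)
    p@heartRate <- 60
    s <- generateMbrSeries(p, nFrames = 118, frameRate = 30, seed = sd,
                           phaseOffset = 0, noiseSd = 0)
    wi <- waveformProfile(s)
    v <- analyticCycle(p, 30)
    binPct <- 100 / 30
    expect_equal(wi@bot, oracleBot(v), tolerance = binPct)
    expect_equal(wi@ati, oracleAti(v), tolerance = binPct)
    expect_equal(wi@bos, oracleBos(v), tolerance = 2)
    expect_equal(wi@ri, oracleRi(v), tolerance = 0.05)
    expect_equal(wi@meanMbr, mean(v), tolerance = 0.02 * mean(v))
    rts <- oracleRates(v)
    expect_equal(wi@rr, unname(rts["rr"]), tolerance = 0.15 * rts["rr"])
    expect_equal(wi@fr, unname(rts["fr"]), tolerance = 0.15 * rts["fr"])
  }
  expect_error(waveformProfile(MbrSeries(rep(1, 100))), "no cardiac cycle")
})
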