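# Composite map, ellipsoid ROI, vessel extraction and regional MBR.

makeTestScene <- function(...) {
  makeScene(height = 90, width = 120, semiAxes = c(40, 30),
            tissueFlowScale = 10, vesselFlowScale = 40, seed = 3, ...)
}

test_that("composite map reduces to the frame for identical frames and is linear", {
  f <- matrix(runif(30 * 40, 5, 20), 30, 40)
  st <- new("FlowMapStack", frames = array(rep(f, 60), c(30, 40, 60)),
            frameRate = 30)
  seg <- new("CycleSegmentation", boundaries = c(1L, 31L), frameRate = 30)
  expect_equal(mapValues(compositeMap(st, seg)), f, tolerance = 1e-12)
  st2 <- new("FlowMapStack", frames = st@frames * 3, frameRate = 30)
  expect_equal(mapValues(compositeMap(st2, seg)),
               3 * mapValues(compositeMap(st, seg)), tolerance = 1e-12)
})

test_that("composite map equals the analytic time mean at zero noise", {
  scene <- makeTestScene()
  p <- simulateSubject(35, "male", seed = 7)
  p@heartRate <- 60
  st <- generateFlowMapStack(p, scene, nFrames = 61, frameRate = 30,
                             seed = 1, noiseSd = 0)
  seg <- new("CycleSegmentation", boundaries = c(1L, 31L, 61L),
             frameRate = 30)
  cm <- compositeMap(st, seg)
  # complete-cycle time mean of the normalized waveform is ~1, so composite
  # pixels sit at their region's flow scale
  expect_equal(mean(mapValues(cm)[!scene@vesselMask]),
               scene@tissueFlowScale, tolerance = 0.01 * scene@tissueFlowScale)
  expect_equal(mean(mapValues(cm)[scene@vesselMask]),
               scene@vesselFlowScale, tolerance = 0.01 * scene@vesselFlowScale)
})

test_that("ROI mask area approximates the ellipse area and rotation is consistent", {
  f <- new("CompositeMap", values = matrix(1, 200, 200))
  r <- 50
  m <- roiMask(f, EllipseRoi(c(100, 100), c(r, r)))
  expect_equal(sum(m), pi * r^2, tolerance = 0.02 * pi * r^2)
  mA <- roiMask(f, EllipseRoi(c(100, 100), c(60, 30), rotation = 90))
  mB <- roiMask(f, EllipseRoi(c(100, 100), c(30, 60)))
  # identical up to pixels exactly on the ellipse boundary, where the
  # floating-point rotation can tip the inclusive test either way
  expect_lte(sum(xor(mA, mB)), 4)
  expect_equal(sum(mA), sum(mB), tolerance = 4)
  # a point outside the bounding box is excluded
  expect_false(mA[100, 35])
  expect_error(roiMask(f, EllipseRoi(c(10, 10), c(40, 40))),
               "outside the frame")
})

test_that("vessel extraction recovers a separable scene exactly", {
  scene <- makeTestScene()
  base <- ifelse(scene@vesselMask, 40, 10)
  cm <- new("CompositeMap", values = base)
  mask <- roiMask(cm, scene@roi)
  vx <- extractVessels(cm, mask)
  expect_gt(vx$threshold, 10)
  expect_lt(vx$threshold, 40)
  expect_identical(vx$vesselMask, mask & scene@vesselMask)
  expect_error(extractVessels(new("CompositeMap",
                                  values = matrix(5, 90, 120)), mask),
               "contrast")
})

test_that("vessel extraction stays accurate under 10% pixel noise", {
  scene <- makeTestScene()
  p <- simulateSubject(35, "male", seed = 7)
  st <- generateFlowMapStack(p, scene, nFrames = 70, frameRate = 30,
                             seed = 5, noiseSd = 0.1 * scene@tissueFlowScale)
  res <- analyzeStack(st, scene@roi)
  gt <- res$mask & scene@vesselMask
  acc <- mean((res$vesselMask == gt)[res$mask])
  expect_gte(acc, 0.95)
})

test_that("the automatic threshold is translation-equivariant", {
  scene <- makeTestScene()
  set.seed(1)
  vals <- ifelse(scene@vesselMask, 40, 10) + rnorm(90 * 120)
  cm <- new("CompositeMap", values = pmax(vals, 0))
  mask <- roiMask(cm, scene@roi)
  t1 <- extractVessels(cm, mask)$threshold
  t2 <- extractVessels(new("CompositeMap", values = cm@values + 7),
                       mask)$threshold
  expect_equal(t2 - t1, 7, tolerance = 1e-9)
})

test_that("regional MBR obeys the exact weighted-mean decomposition", {
  scene <- makeTestScene()
  base <- ifelse(scene@vesselMask, 40, 10)
  cm <- new("CompositeMap", values = base)
  mask <- roiMask(cm, scene@roi)
  vmask <- mask & scene@vesselMask
  om <- regionalMbr(cm, mask, vmask)
  expect_equal(om@mv, 40); expect_equal(om@mt, 10)
  f <- sum(vmask) / sum(mask)
  expect_equal(om@ma, f * 40 + (1 - f) * 10, tolerance = 1e-12)
  # identity on an arbitrary noisy map
  set.seed(2)
  cm2 <- new("CompositeMap", values = pmax(base + rnorm(length(base), 0, 4), 0))
  om2 <- regionalMbr(cm2, mask, vmask)
  expect_equal(om2@ma,
               om2@vesselFraction * mean(cm2@values[vmask]) +
                 (1 - om2@vesselFraction) * mean(cm2@values[mask & !vmask]),
               tolerance = 1e-12)
  # a uniform ROI value collapses all three means
  cm3 <- new("CompositeMap", values = matrix(6, 90, 120))
  om3 <- regionalMbr(cm3, mask, vmask)
  expect_equal(c(om3@ma, om3@mv, om3@mt), c(6, 6, 6))
  # hand-built two-level ROI: 10 tissue / 40 vessel at fraction 0.25
  vals <- matrix(10, 20, 20); vals[1:10, 1:10] <- 40
  msk <- matrix(TRUE, 20, 20); vsk <- vals == 40
  om4 <- regionalMbr(new("CompositeMap", values = vals), msk, vsk)
  expect_equal(om4@ma, 17.5)
  expect_equal(om4@mv, 40)
  expect_equal(om4@mt, 10)
})

test_that("an end-to-end stack analysis reproduces MV > MA > MT ordering", {
  scene <- makeTestScene()
  p <- simulateSubject(45, "female", seed = 11)
  st <- generateFlowMapStack(p, scene, nFrames = 70, frameRate = 30,
                             seed = 2, noiseSd = 0.5)
  res <- analyzeStack(st, scene@roi)
  om <- res$measurement
  expect_true(om@mv > om@ma && om@ma > om@mt)
  expect_true(validObject(om))
})

test_that("ROI and stack files round-trip", {
  roi <- EllipseRoi(c(60.5, 45.25), c(40, 30), rotation = 12)
  f <- tempfile(fileext = ".json")
  writeRoiJson(roi, f)
  roi2 <- readRoiJson(f)
  expect_equal(roi2@center, roi@center)
  expect_equal(roi2@semiAxes, roi@semiAxes)
  expect_equal(roi2@rotation, roi@rotation)
  st <- new("FlowMapStack",
            frames = array(runif(10 * 12 * 5, 0, 20), c(10, 12, 5)),
            frameRate = 30)
  sf <- tempfile()
  writeFlowMapStack(st, sf)
  st2 <- readFlowMapStack(sf)
  expect_equal(st2@frames, st@frames)
  expect_equal(st2@frameRate, 30)
})
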