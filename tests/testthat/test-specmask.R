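test_that("detection trivial cases behave as the rule dictates", {
  black <- array(0, c(32, 32, 3))
  expect_true(all(detectSpecularMask(black) == 0))

  red <- array(rep(c(0.6, 0.2, 0.2), each = 32 * 32), c(32, 32, 3))
  expect_true(all(detectSpecularMask(red) == 0))

  expect_error(detectSpecularMask(matrix(0, 8, 8)), "RGB")
})

test_that("detection matches the per-pixel oracle on small frames", {
  params <- detectionParams(minRegionArea = 1L, localWindow = 5L)
  for (s in 1:3) {
    set.seed(s)
    fr <- array(runif(24 * 24 * 3, 0, 0.6), c(24, 24, 3))
    # plant a saturated desaturated blob
    fr[8:11, 8:11, ] <- 0.97
    got <- detectSpecularMask(fr, params)
    want <- oracleDetect(fr, params)
    expect_equal(got, want)
  }
})

test_that("detection covers the saturated core of a synthetic highlight", {
  spec <- syntheticSceneSpec(
    frameCount = 1, frameSize = c(48, 48),
    motion = list(driftPx = 0, rotDeg = 0, wobble = 0),
    highlights = list(count = 1, radiusRange = c(6, 6), saturation = 1,
                      ringWidth = 2, ringDarken = 0.55, jumpProb = 0,
                      visibleProb = 1),
    seed = 5)
  syn <- generateClip(spec)
  det <- detectSpecularMask(syn$corrupted[[1]])
  # per-pixel absolute-rule oracle: every very-bright desaturated pixel
  fr <- syn$corrupted[[1]]
  v <- pmax(fr[, , 1], pmax(fr[, , 2], fr[, , 3]))
  mn <- pmin(fr[, , 1], pmin(fr[, , 2], fr[, , 3]))
  core <- v > 0.85 & (v - mn) / pmax(v, 1e-12) < 0.25
  expect_true(all(det[core] == 1))
  expect_gt(sum(det), 0)
})

test_that("dilation matches the brute-force morphology oracle", {
  expect_true(all(dilateMask(matrix(0, 9, 9), "diamond", 2) == 0))

  single <- matrix(0, 9, 9); single[5, 5] <- 1
  plus <- dilateMask(single, "diamond", 1)
  expect_equal(sum(plus), 5)
  expect_equal(plus[4:6, 5], c(1, 1, 1))
  expect_equal(plus[5, 4:6], c(1, 1, 1))

  set.seed(42)
  m <- matrix(rbinom(32 * 32, 1, 0.05), 32, 32)
  for (el in list(list("ellipse", c(3, 2)), list("ball", 2),
                  list("diamond", 2))) {
    got <- dilateMask(m, el[[1]], el[[2]])
    want <- oracleDilate(m, structuringElement(el[[1]], el[[2]]))
    expect_equal(got, want, info = el[[1]])
  }
  expect_error(dilateMask(m, "ball", -1), "radius")
})

test_that("dilation is monotone and distributes over union", {
  set.seed(1)
  A <- matrix(rbinom(24 * 24, 1, 0.06), 24, 24)
  B <- matrix(rbinom(24 * 24, 1, 0.06), 24, 24)
  dA <- dilateMask(A, "ball", 2)
  expect_true(all(dA >= A))
  dU <- dilateMask(pmax(A, B), "ball", 2)
  expect_equal(dU, pmax(dA, dilateMask(B, "ball", 2)))
})

test_that("pseudo masks implement translate / dilate / overlap removal", {
  expect_true(all(makePseudoMask(matrix(0, 20, 20),
                                 pseudoGTSpec(c(5, 0))) == 0))

  # pure shift: no dilation, far translation
  m <- matrix(0, 40, 40); m[11:13, 11:13] <- 1
  sp <- pseudoGTSpec(c(20, 0), guardRadius = 0, ellipseRadii = c(0, 0),
                     diamondRadius = 0)
  got <- makePseudoMask(m, sp)
  want <- matrix(0, 40, 40); want[11:13, 31:33] <- 1
  expect_equal(got, want)

  # crescent: disc translated by less than its diameter, oracle by pixel sets
  H <- 32
  disc <- oracleDisc(H, H, 16, 16, 4)
  sp2 <- pseudoGTSpec(c(4, 0), guardRadius = 1, ellipseRadii = c(0, 0))
  got2 <- makePseudoMask(disc, sp2)
  shifted <- oracleDisc(H, H, 16, 20, 4)
  guard <- oracleDilate(disc, structuringElement("ball", 1))
  expect_equal(got2, shifted * (1 - guard))

  expect_error(pseudoGTSpec(c(0, 0)), "translation")
})

test_that("both pseudo-GT variants stay disjoint from the guard-dilated original", {
  syn <- generateClip(syntheticSceneSpec(frameCount = 6,
                                         frameSize = c(64, 64), seed = 3))
  det <- detectSpecularClip(syn$corrupted)
  for (variant in c("training", "evaluation")) {
    sp <- pseudoGTSpec(c(13, 0), guardRadius = 3, ellipseRadii = c(5, 3),
                       variant = variant)
    res <- makePseudoMasks(detections = det, spec = sp)
    for (t in 1:6) {
      guard <- dilateMask(res$segmentation[[t]], "ball", 3)
      expect_equal(sum(res$pseudo[[t]] * guard), 0, info = variant)
    }
    expect_equal(res$translation, c(13, 0))
  }
})

test_that("Bezier random masks keep a constant shape moving smoothly", {
  m1 <- bezierRandomMasks(1, c(64, 64), seed = 5)
  expect_equal(nFrames(m1), 1)
  expect_gt(sum(m1[[1]]), 0)

  cp <- matrix(rep(c(30, 30), each = 4), 4, 2)
  stat <- bezierRandomMasks(5, c(64, 64), seed = 5, controlPoints = cp)
  for (t in 2:5) expect_identical(stat[[t]], stat[[1]])

  mv <- bezierRandomMasks(24, c(288, 288), seed = 5, shapeRadius = 14)
  areas <- vapply(1:24, function(t) sum(mv[[t]]), numeric(1))
  expect_true(all(areas > 0))
  # smoothness: consecutive-frame IoU stays high because the per-step
  # centroid displacement is bounded by the Bezier derivative
  for (t in 2:24) {
    a <- mv[[t - 1]]; b <- mv[[t]]
    iou <- sum(a * b) / sum(pmax(a, b))
    expect_gte(iou, 0.5)
  }
  expect_error(bezierRandomMasks(0, c(64, 64)), "T")
})
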