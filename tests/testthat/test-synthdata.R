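test_that("clip generation is deterministic and respects the highlight count", {
  spec <- syntheticSceneSpec(frameCount = 4, frameSize = c(48, 48), seed = 7)
  a <- generateClip(spec)
  b <- generateClip(spec)
  expect_identical(frames(a$clean), frames(b$clean))
  expect_identical(masks(a$masks), masks(b$masks))
  expect_identical(frames(a$corrupted), frames(b$corrupted))

  spec0 <- syntheticSceneSpec(frameCount = 3, frameSize = c(48, 48),
                              highlights = list(count = 0,
                                                radiusRange = c(3, 8),
                                                saturation = 1, ringWidth = 2,
                                                ringDarken = 0.55,
                                                jumpProb = 0.2,
                                                visibleProb = 1),
                              seed = 2)
  z <- generateClip(spec0)
  expect_true(all(masks(z$masks) == 0))
  expect_identical(frames(z$corrupted), frames(z$clean))
})

test_that("clean and corrupted frames differ only inside the masks", {
  syn <- generateClip(syntheticSceneSpec(frameCount = 5,
                                         frameSize = c(48, 48), seed = 11))
  for (t in 1:5) {
    diff <- abs(syn$clean[[t]] - syn$corrupted[[t]])
    changed <- apply(diff, c(1, 2), max) > 0
    expect_true(all(syn$masks[[t]][changed] == 1))
  }
})

test_that("a single static blob produces the disc mask of the rasterisation oracle", {
  spec <- syntheticSceneSpec(
    frameCount = 3, frameSize = c(40, 40),
    motion = list(driftPx = 0, rotDeg = 0, wobble = 0),
    highlights = list(count = 1, radiusRange = c(5, 5), saturation = 1,
                      ringWidth = 0, ringDarken = 1, jumpProb = 0,
                      visibleProb = 1, centers = c(20.5, 20.5), jitterSd = 0),
    seed = 4)
  syn <- generateClip(spec)
  # static blob pinned at the frame centre: the mask must equal the
  # brute-force rasterised disc exactly in every frame
  for (t in 1:3) {
    m <- syn$masks[[t]]
    oracle <- oracleDisc(40, 40, 20.5, 20.5, 5)
    expect_equal(sum(m), sum(oracle))
    expect_true(all(m == oracle))
  }
})

test_that("invalid scene specs are rejected", {
  expect_error(syntheticSceneSpec(frameCount = 0), "frameCount")
  expect_error(syntheticSceneSpec(frameSize = c(16, 64)), "frameSize")
  hp <- list(count = 1, radiusRange = c(3, 8), saturation = 1, ringWidth = 2,
             ringDarken = 0.55, jumpProb = 1.5, visibleProb = 1)
  expect_error(syntheticSceneSpec(highlights = hp), "jumpProb")
})

test_that("noiseless two-view scenes satisfy the exact epipolar constraint", {
  for (s in 1:5) {
    sc <- generateTwoViewScene(60, rotationDeg = 12,
                               translation = c(0.4, -0.1, 0.2),
                               noisePx = 0, seed = s)
    E <- essentialMatrixGT(sc)
    K <- sc@intrinsics
    x1 <- solve(K) %*% rbind(t(sc@proj1), 1)
    x2 <- solve(K) %*% rbind(t(sc@proj2), 1)
    resid <- abs(colSums(x2 * (E %*% x1)))
    expect_lt(max(resid), 1e-9)
    expect_equal(det(sc@rotationGT), 1, tolerance = 1e-9)
  }
})

test_that("two-view generator enforces its preconditions", {
  expect_error(generateTwoViewScene(4, 10, c(1, 0, 0)), "nPoints")
  expect_error(generateTwoViewScene(20, 10, c(0, 0, 0)), "translation")
})

test_that("noiseless scenes are recoverable end-to-end by the pose module", {
  sc <- generateTwoViewScene(100, rotationDeg = 10,
                             translation = c(1, 0, 0), noisePx = 0, seed = 3)
  est <- estimateRelativePose(list(ptsA = sc@proj1, ptsB = sc@proj2),
                              sc@intrinsics, seed = 3)
  expect_lt(rotationError(est$R, sc@rotationGT), 0.1)
  expect_lt(translationError(est$t, sc@translationGT), 0.5)
})

test_that("stereo pairs follow the disparity warp exactly", {
  spec <- syntheticSceneSpec(frameCount = 1, frameSize = c(48, 48), seed = 9)
  z <- generateStereoPair(spec, matrix(0, 48, 48))
  expect_equal(z$left, z$right, tolerance = 1e-12)

  ramp <- generateStereoPair(spec, function(rows, cols)
    8 * (cols - 1) / 47)
  # independent per-pixel remap oracle on interior pixels
  d <- ramp$disparityGT
  for (pt in list(c(10, 10), c(25, 30), c(40, 5))) {
    r <- pt[1]; cc <- pt[2]
    src <- cc + d[r, cc]
    if (src <= 47) {
      c0 <- floor(src); fr <- src - c0
      for (ch in 1:3) {
        want <- ramp$left[r, c0, ch] * (1 - fr) + ramp$left[r, c0 + 1, ch] * fr
        expect_equal(ramp$right[r, cc, ch], want, tolerance = 1e-12)
      }
    }
  }
  expect_error(generateStereoPair(spec, matrix(-1, 48, 48)), "nonnegative")
})

test_that("disparity metrics on the ground truth itself are zero", {
  spec <- syntheticSceneSpec(frameCount = 1, frameSize = c(48, 48), seed = 9)
  ramp <- generateStereoPair(spec, function(rows, cols) 4 + 0 * cols)
  ev <- disparityErrors(ramp$disparityGT, ramp$disparityGT,
                        matrix(1, 48, 48))
  expect_equal(ev$RMS, 0)
  expect_equal(ev$EPE, 0)
  expect_equal(ev$Bad3, 0)
})
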