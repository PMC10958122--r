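# textured frame with corners for feature tests
texturedFrame <- function(H, W, seed = 3) {
  set.seed(seed)
  base <- matrix(runif((H + 40) * (W + 40)), H + 40, W + 40)
  sm <- SpecFill:::sepConv(base, SpecFill:::gaussKernel1d(5, 1))
  sm
}

test_that("feature matching finds itself and known shifts", {
  g <- texturedFrame(160, 160)[1:120, 1:120]
  ms <- matchFeatures(g, g, maxFeatures = 300)
  expect_gt(nrow(ms@matches), 20)
  dA <- ms@keypointsA[ms@matches[, 1], , drop = FALSE]
  dB <- ms@keypointsB[ms@matches[, 2], , drop = FALSE]
  disp <- sqrt(rowSums((dA - dB)^2))
  expect_lt(mean(disp), 1)

  big <- texturedFrame(160, 200)
  a <- big[21:140, 21:150]
  b <- big[21:140, 31:160] # 10 px horizontal shift
  ms2 <- matchFeatures(a, b, maxFeatures = 300)
  expect_gt(nrow(ms2@matches), 10)
  dA <- ms2@keypointsA[ms2@matches[, 1], , drop = FALSE]
  dB <- ms2@keypointsB[ms2@matches[, 2], , drop = FALSE]
  expect_equal(median(dA[, "x"] - dB[, "x"]), 10, tolerance = 1)
  expect_equal(median(dA[, "y"] - dB[, "y"]), 0, tolerance = 1)

  blank <- matrix(0.5, 100, 100)
  mb <- matchFeatures(blank, blank)
  expect_equal(nrow(mb@matches), 0)
  expect_true(nzchar(mb@flag))
})

test_that("lowering the ratio threshold never increases the match count", {
  big <- texturedFrame(160, 200, seed = 8)
  a <- big[21:140, 21:150]; b <- big[21:140, 26:155]
  counts <- vapply(c(0.9, 0.75, 0.6, 0.4), function(r)
    nrow(matchFeatures(a, b, maxFeatures = 300, ratio = r)@matches),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("dense flow converts to correspondences and recovers known warps", {
  flow <- array(0, c(40, 40, 2))
  ms <- flowToMatches(flow, stride = 8)
  dA <- ms@keypointsA; dB <- ms@keypointsB
  expect_equal(dA, dB)

  flow[, , 1] <- 5; flow[, , 2] <- -3
  ms2 <- flowToMatches(flow, stride = 8)
  expect_true(all(ms2@keypointsB[, "x"] - ms2@keypointsA[, "x"] == 5))
  expect_true(all(ms2@keypointsB[, "y"] - ms2@keypointsA[, "y"] == -3))
  expect_error(flowToMatches(flow, stride = 50), "stride")

  # analytic rotation warp about the centre
  th <- 2 * pi / 180
  rows <- matrix(1:40, 40, 40); cols <- matrix(1:40, 40, 40, byrow = TRUE)
  cx <- 20.5
  flow[, , 1] <- cos(th) * (cols - cx) - sin(th) * (rows - cx) + cx - cols
  flow[, , 2] <- sin(th) * (cols - cx) + cos(th) * (rows - cx) + cx - rows
  ms3 <- flowToMatches(flow, stride = 4)
  for (k in seq_len(nrow(ms3@matches))) {
    p <- ms3@keypointsA[k, ]; q <- ms3@keypointsB[k, ]
    wantX <- cos(th) * (p["x"] - cx) - sin(th) * (p["y"] - cx) + cx
    wantY <- sin(th) * (p["x"] - cx) + cos(th) * (p["y"] - cx) + cx
    expect_equal(unname(q["x"]), unname(wantX), tolerance = 1e-9)
    expect_equal(unname(q["y"]), unname(wantY), tolerance = 1e-9)
  }
})

test_that("the pyramidal flow estimator recovers a constant translation", {
  big <- texturedFrame(120, 160, seed = 5)
  a <- big[21:100, 21:120]
  b <- big[21:100, 25:124] # content appears 4 px to the left in b
  fl <- estimateFlow(a, b)
  inner <- fl[20:60, 20:80, ]
  expect_equal(median(inner[, , 1]), -4, tolerance = 0.5)
  expect_equal(median(inner[, , 2]), 0, tolerance = 0.5)
})

test_that("the five-point solver recovers ground-truth essential matrices", {
  set.seed(6)
  for (trial in 1:5) {
    axis <- rnorm(3)
    R <- SpecFill:::axisAngleRotation(axis, runif(1, 3, 25))
    tv <- rnorm(3); tv <- tv / sqrt(sum(tv^2))
    E <- SpecFill:::skew3(tv) %*% R
    X <- cbind(runif(5, -1, 1), runif(5, -1, 1), runif(5, 2, 5))
    x1 <- X[, 1:2] / X[, 3]
    X2 <- t(R %*% t(X) + tv)
    x2 <- X2[, 1:2] / X2[, 3]
    sols <- fivePointEssential(x1, x2)
    En <- E / sqrt(sum(E^2))
    best <- min(vapply(sols, function(S)
      min(max(abs(S - En)), max(abs(S + En))), numeric(1)))
    expect_lt(best, 1e-6)
    # every returned solution annihilates the five correspondences
    for (S in sols) {
      resid <- abs(colSums(rbind(t(x2), 1) * (S %*% rbind(t(x1), 1))))
      expect_lt(max(resid), 1e-8)
    }
  }
  expect_error(fivePointEssential(matrix(0, 4, 2), matrix(0, 4, 2)), "five")
})

test_that("pose recovery is accurate, robust to outliers, and flags rotation-only scenes", {
  maxRRE <- 0; maxRTE <- 0
  for (s in 1:15) {
    sc <- generateTwoViewScene(100, rotationDeg = 10,
                               translation = c(0.3, 0.05, 0.1),
                               noisePx = 0, seed = s)
    est <- estimateRelativePose(list(ptsA = sc@proj1, ptsB = sc@proj2),
                                sc@intrinsics, seed = s)
    expect_false(est$degenerate)
    maxRRE <- max(maxRRE, rotationError(est$R, sc@rotationGT))
    maxRTE <- max(maxRTE, translationError(est$t, sc@translationGT))
    # Sampson residuals of inliers below the threshold by construction
    expect_gte(est$inliers, 95)
  }
  expect_lt(maxRRE, 0.1)
  expect_lt(maxRTE, 0.5)

  # 40% gross outliers
  sc <- generateTwoViewScene(200, 8, c(0.4, 0, 0.1), 0, seed = 99)
  pB <- sc@proj2
  set.seed(7)
  bad <- sample(200, 80)
  pB[bad, ] <- cbind(runif(80, 1, 640), runif(80, 1, 480))
  est <- estimateRelativePose(list(ptsA = sc@proj1, ptsB = pB),
                              sc@intrinsics, seed = 5)
  expect_lt(rotationError(est$R, sc@rotationGT), 0.5)
  expect_gte(est$inliers, 110)

  # pure rotation: translation direction unobservable
  set.seed(3)
  K <- sc@intrinsics
  R <- SpecFill:::axisAngleRotation(c(0, 1, 0), 5)
  X <- cbind(runif(100, -1, 1), runif(100, -0.8, 0.8), runif(100, 2.5, 6))
  p1 <- t(K %*% t(X / X[, 3]))[, 1:2]
  X2 <- t(R %*% t(X))
  p2 <- t(K %*% t(X2 / X2[, 3]))[, 1:2]
  estR <- estimateRelativePose(list(ptsA = p1, ptsB = p2), K, seed = 2)
  expect_true(estR$degenerate)

  expect_error(estimateRelativePose(list(ptsA = p1[1:3, ], ptsB = p2[1:3, ]),
                                    K), "5 matches")
})

test_that("rotation and translation errors match independent oracles", {
  I3 <- diag(3)
  expect_equal(rotationError(I3, I3), 0)
  Rz <- SpecFill:::axisAngleRotation(c(0, 0, 1), 90)
  expect_equal(rotationError(Rz, I3), 90, tolerance = 1e-9)
  set.seed(14)
  for (k in 1:5) {
    Ra <- SpecFill:::axisAngleRotation(rnorm(3), runif(1, 0, 170))
    Rb <- SpecFill:::axisAngleRotation(rnorm(3), runif(1, 0, 170))
    want <- oracleRotationAngleDeg(Ra %*% t(Rb))
    expect_equal(rotationError(Ra, Rb), want, tolerance = 1e-6)
  }
  expect_error(rotationError(matrix(1, 3, 3), I3), "orthonormal")

  expect_equal(translationError(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(translationError(c(1, 0, 0), c(-1, 0, 0)), 0)
  expect_equal(translationError(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_error(translationError(c(0, 0, 0), c(1, 0, 0)), "zero-norm")
})

test_that("window pairs enumerate the moving-window frame pairs", {
  p <- windowPairs(40, 20)
  expect_equal(nrow(p), 20)
  expect_equal(unname(p[1, ]), c(1, 21))
  expect_equal(unname(p[20, ]), c(20, 40))
  expect_equal(nrow(windowPairs(21, 20)), 1)
  e <- windowPairs(20, 20)
  expect_equal(nrow(e), 0)
  expect_match(attr(e, "flag"), "shorter")
})

test_that("pose-error summaries use linear-interpolation quantiles on paired deltas", {
  o <- data.frame(pair = 1:4, RTE = c(4, 3, 6, 9), RRE = c(1, 1, 2, 3),
                  inliers = c(10, 20, 30, 40))
  i <- data.frame(pair = 1:4, RTE = c(5, 3, 5, 7), RRE = c(1, 1, 2, 3),
                  inliers = c(10, 20, 30, 40))
  s <- summarizePoseErrors(o, i)
  rte <- s[s$metric == "RTE", ] # deltas {-1, 0, 1, 2}
  expect_equal(rte$median, 0.5)
  expect_equal(rte$p25, -0.25)
  expect_equal(rte$p75, 1.25)
  expect_equal(rte$iqr, 1.5)
  rre <- s[s$metric == "RRE", ]
  expect_equal(c(rre$min, rre$max, rre$mean, rre$median), rep(0, 4))

  # permutation invariance of the pairing
  s2 <- summarizePoseErrors(o[c(3, 1, 4, 2), ], i[c(2, 4, 1, 3), ])
  expect_equal(s2, s)
  expect_error(summarizePoseErrors(o, i[1:3, ]), "pair sets")
})
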