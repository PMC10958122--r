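test_that("patch similarity is the normalised dot product", {
  expect_equal(patchSimilarity(numeric(4), numeric(4), 2, 1, 2), 0)
  expect_equal(patchSimilarity(c(1, 2), c(3, 4), 1, 1, 2), 5.5)
  expect_equal(patchSimilarity(c(1, 0), c(0, 1), 1, 1, 2), 0)
  expect_error(patchSimilarity(1:3, 1:4, 1, 1, 3), "length")
})

test_that("attention weights are a validity-masked softmax", {
  w <- attentionWeights(c(0, 0), c(TRUE, TRUE))
  expect_equal(w$weights, c(0.5, 0.5))
  expect_false(w$degenerate)

  w2 <- attentionWeights(c(log(2), 0), c(TRUE, TRUE))
  expect_equal(w2$weights, c(2 / 3, 1 / 3))

  w3 <- attentionWeights(c(5, -1), c(TRUE, FALSE))
  expect_equal(w3$weights, c(1, 0))

  w4 <- attentionWeights(c(1, 2), c(FALSE, FALSE))
  expect_true(w4$degenerate)
  expect_equal(w4$weights, c(0, 0))

  expect_error(attentionWeights(c(NaN, 1), c(TRUE, TRUE)), "NaN")
})

test_that("attend forms the weighted sum of value patches", {
  V <- matrix(1:12, 4, 3)
  expect_equal(attend(c(0, 1, 0, 0), V), V[2, ])
  expect_equal(attend(rep(0.25, 4), V), colMeans(V))
  set.seed(3)
  a <- runif(4); a <- a / sum(a)
  brute <- a[1] * V[1, ] + a[2] * V[2, ] + a[3] * V[3, ] + a[4] * V[4, ]
  expect_equal(attend(a, V), brute)
  expect_error(attend(c(1, 0), V), "length")
})

test_that("the encoder is frame-level and obeys the shape contract", {
  cfg <- tinyTransformerConfig()
  st <- initGenerator(cfg, seed = 1)
  set.seed(2)
  Y <- array(runif(64 * 64 * 3 * 3, -1, 1), c(64, 64, 3, 3))
  M <- array(0, c(64, 64, 3))
  f <- encodeFrames(Y, M, st)
  expect_equal(dim(f), c(16, 16, 32, 3))

  # identical frames give identical features (no cross-frame coupling)
  Y2 <- Y
  Y2[, , , 2] <- Y[, , , 1]
  Y2[, , , 3] <- Y[, , , 1]
  f2 <- encodeFrames(Y2, M, st)
  expect_equal(f2[, , , 2], f2[, , , 1])
  expect_equal(f2[, , , 3], f2[, , , 1])
  expect_error(encodeFrames(Y, array(0, c(32, 32, 3)), st), "mismatch")
})

test_that("patch fold/extract is an exact round trip at every head scale", {
  set.seed(8)
  x <- array(rnorm(16 * 16 * 6 * 3), c(16, 16, 6, 3))
  for (hd in list(c(16, 16), c(8, 8), c(4, 4), c(2, 2), c(4, 8))) {
    M <- SpecFill:::extractPatches(x, hd[1], hd[2])
    back <- SpecFill:::foldPatches(M, 16, 16, 6, 3, hd[1], hd[2])
    expect_identical(back, x)
  }
})

test_that("transformer forward matches the unbatched reference implementation", {
  cfg <- tinyTransformerConfig() # 16x16 features, heads (8,8) and (4,4)
  st <- initGenerator(cfg, seed = 5)
  set.seed(9)
  T <- 3
  f <- array(rnorm(16 * 16 * 32 * T, 0, 0.5), c(16, 16, 32, T))
  M <- array(0, c(64, 64, T))
  M[9:14, 33:40, 1] <- 1 # hole in frame 1 only
  got <- transformerForward(f, M, st)
  mf <- oracleBlockMax(M, 4)
  want <- f
  for (l in seq_len(cfg$layers))
    want <- oracleAttnLayer(want, st$params, l, cfg, mf)
  expect_equal(got, want, tolerance = 1e-10)
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("attention rows are row-stochastic with invalid entries exactly zero", {
  cfg <- tinyTransformerConfig(layers = 1)
  st <- initGenerator(cfg, seed = 2)
  set.seed(4)
  T <- 3
  f <- array(rnorm(16 * 16 * 32 * T), c(16, 16, 32, T))
  M <- array(0, c(64, 64, T))
  M[1:12, 1:16, ] <- 1
  res <- transformerForward(f, M, st, returnAttention = TRUE)
  for (l in seq_along(res$attention)) for (g in seq_along(res$attention[[l]])) {
    A <- res$attention[[l]][[g]]$A
    valid <- res$validity[[g]]
    expect_true(all(A >= 0))
    expect_true(all(A[, !valid] == 0))
    if (any(valid)) {
      rs <- rowSums(A)
      expect_lt(max(abs(rs - 1)), 1e-6)
    }
  }
})

test_that("an all-hole mask degenerates gracefully with finite output", {
  cfg <- tinyTransformerConfig(layers = 1)
  st <- initGenerator(cfg, seed = 2)
  set.seed(4)
  f <- array(rnorm(16 * 16 * 32 * 2), c(16, 16, 32, 2))
  M <- array(1, c(64, 64, 2))
  res <- transformerForward(f, M, st, returnAttention = TRUE)
  expect_true(all(is.finite(res$features)))
  for (g in seq_along(res$attention[[1]]))
    expect_true(all(res$attention[[1]][[g]]$degenerate))
})

test_that("inpainting is the identity under compositing with empty masks", {
  cfg <- tinyTransformerConfig()
  st <- initGenerator(cfg, seed = 3)
  syn <- generateClip(syntheticSceneSpec(frameCount = 6,
                                         frameSize = c(64, 64), seed = 12))
  zeroM <- MaskSequence(array(0, c(64, 64, 6)))
  out <- inpaintClip(syn$clean, zeroM, st)
  expect_identical(frames(out), frames(syn$clean))

  # single-frame clip runs as pure spatial inpainting
  one <- VideoClip(frames(syn$clean)[, , , 1, drop = FALSE])
  m1 <- MaskSequence(masks(syn$masks)[, , 1, drop = FALSE])
  o1 <- inpaintClip(one, m1, st, temporal = FALSE)
  expect_equal(dim(frames(o1)), dim(frames(one)))
  expect_error(inpaintClip(syn$clean, m1, st), "mismatch")
})

test_that("distant conditioning frames are sampled at the configured stride", {
  win <- sampleTrainingWindow(50, 26, 2, 10)
  expect_equal(win, sort(unique(c(24:28, c(1, 11, 21, 31, 41)))))
  expect_equal(sampleTrainingWindow(10, 1, 0, 10), 1)
  expect_equal(sampleTrainingWindow(10, 5, 0, 10), c(1, 5))
  expect_equal(min(sampleTrainingWindow(50, 1, 2, 10)), 1)
  expect_error(sampleTrainingWindow(10, 0, 1, 5), "outside")
})

test_that("the discriminator obeys shape, zero-critic and independence contracts", {
  cfg <- tinyTransformerConfig()
  dz <- initDiscriminator(cfg, seed = 1, zeroInit = TRUE)
  set.seed(6)
  x <- array(runif(64 * 64 * 3 * 6), c(64, 64, 3, 6))
  sc <- discriminatorScore(x, dz)
  expect_equal(dim(sc), c(6, 8, 8))
  expect_true(all(sc == 0))
  expect_equal(lossDiscriminator(sc, sc), 2)

  dr <- initDiscriminator(cfg, seed = 2)
  s1 <- discriminatorScore(x, dr)
  expect_true(any(s1 != 0))
  expect_error(discriminatorScore(x[, , , 1:2, drop = FALSE], dr),
               "receptive depth")
})
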