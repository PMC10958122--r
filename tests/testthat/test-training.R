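test_that("reconstruction losses match hand-computed values", {
  Y <- matrix(c(1, 0, 0, 0), 2, 2)
  Yhat <- matrix(0, 2, 2)
  M <- matrix(c(1, 0, 1, 0), 2, 2) # holes at (1,1) and (1,2)
  expect_equal(lossHole(Y, Y, M), 0)
  expect_equal(lossValid(Y, Y, M), 0)
  expect_equal(lossHole(Y, Yhat, M), 0.5)
  expect_equal(lossValid(Y, Yhat, 1 - M), 0.5)
  expect_error(lossHole(Y, Yhat, matrix(0, 2, 2)), "all-zero")
  expect_error(lossValid(Y, Yhat, matrix(1, 2, 2)), "all-one")

  # constant offset on valid pixels
  delta <- 0.3
  expect_equal(lossValid(Y, Y + delta, M), delta)
})

test_that("adversarial and discriminator losses follow the hinge formulation", {
  expect_equal(lossAdv(array(0, c(2, 3))), 0)
  expect_equal(lossAdv(array(0.5, c(4, 4))), -0.5)
  expect_equal(lossAdv(c(1, -1)), 0)
  expect_error(lossAdv(numeric(0)), "empty")

  expect_equal(lossDiscriminator(array(2, 4), array(-2, 4)), 0)
  expect_equal(lossDiscriminator(array(0, 4), array(0, 4)), 2)
  expect_equal(lossDiscriminator(array(1, 4), array(-1, 4)), 0)
  expect_error(lossDiscriminator(numeric(0), 1), "empty")
})

test_that("the total objective is the weighted sum with the default lambdas", {
  # components engineered to be (0.5, 0.5, -0.5)
  Y <- matrix(c(1, 0, 0, 0), 2, 2)
  Yhat0 <- matrix(0, 2, 2)
  M <- matrix(c(1, 0, 1, 0), 2, 2)
  Yh <- Y
  Yh[M == 1] <- Yhat0[M == 1]          # hole error 0.5
  Yh[2, 1] <- Y[2, 1] + 0.5            # one of two valid pixels off by 1?
  Yh[2, 2] <- Y[2, 2] + 0.5            # both valid pixels off by 0.5
  expect_equal(lossHole(Y, Yh, M), 0.5)
  expect_equal(lossValid(Y, Yh, M), 0.5)
  total <- lossTotal(Y, Yh, M, fakeScores = array(0.5, 4), w = lossWeights())
  expect_equal(total, 0.5 + 0.5 - 0.01 * 0.5)
  expect_equal(total, 0.995)

  # lambdaAdv = 0 reduces exactly to the two L1 terms
  w0 <- lossWeights(lambdaAdv = 0)
  expect_equal(lossTotal(Y, Yh, M, w = w0), 1)
})

test_that("hole + valid losses reduce to the full-frame MAE in the balanced case", {
  set.seed(10)
  Y <- matrix(runif(64), 8, 8)
  M <- matrix(0, 8, 8); M[, 1:4] <- 1
  err <- matrix(0.2, 8, 8)
  Yh <- Y + err
  expect_equal(lossHole(Y, Yh, M) + lossValid(Y, Yh, M),
               2 * mean(abs(Y - Yh)))
})

test_that("the analytic objective gradient matches finite differences", {
  cfg <- tinyTransformerConfig()
  set.seed(3)
  Y <- array(runif(4 * 4 * 3 * 4), c(4, 4, 3, 4))
  Yhat <- array(runif(length(Y)), dim(Y))
  M <- array(0, c(4, 4, 4)); M[2:3, 2:3, ] <- 1
  w <- lossWeights()
  disc <- initDiscriminator(cfg, seed = 4)
  lossOf <- function(Yh) {
    sc <- SpecFill:::discForward(2 * Yh - 1, disc$params)$out
    w$lambdaHole * lossHole(Y, Yh, M) + w$lambdaValid * lossValid(Y, Yh, M) +
      w$lambdaAdv * lossAdv(sc)
  }
  df <- SpecFill:::discForward(2 * Yhat - 1, disc$params)
  dscore <- array(-1 / length(df$out), dim(df$out))
  dAdv <- 2 * SpecFill:::discBackward(dscore, disc$params, df$cache)$dx
  g <- SpecFill:::lossL1Grad(Y, Yhat, M, w) + w$lambdaAdv * dAdv
  set.seed(11)
  for (k in 1:12) {
    i <- sample(length(Yhat), 1)
    eps <- 1e-5
    Yp <- Yhat; Yp[i] <- Yp[i] + eps
    Ym <- Yhat; Ym[i] <- Ym[i] - eps
    num <- (lossOf(Yp) - lossOf(Ym)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("generator backpropagation matches finite differences through the net", {
  cfg <- transformerConfig(inputSize = c(16, 16), channels = 8, layers = 1,
                           heads = list(c(4, 4), c(2, 2)),
                           encChannels = c(4, 4, 6), discChannels = 4)
  st <- initGenerator(cfg, seed = 3)
  set.seed(11)
  Y <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  M <- array(0, c(16, 16, 2)); M[5:6, 6:7, ] <- 1
  w <- lossWeights(lambdaAdv = 0)
  lossOf <- function(stx) {
    fw <- SpecFill:::generatorForward(stx, Y, M)
    lossHole(Y, fw$Yhat, M) + lossValid(Y, fw$Yhat, M)
  }
  fw <- SpecFill:::generatorForward(st, Y, M, train = TRUE)
  gr <- SpecFill:::generatorBackward(st, fw$cache,
                                     SpecFill:::lossL1Grad(Y, fw$Yhat, M, w))
  set.seed(5)
  for (nm in c("enc2", "l1.Wq", "l1.Wv", "l1.ffn1", "dec3")) {
    for (trial in 1:2) {
      i <- sample(length(st$params[[nm]]$W), 1)
      eps <- 1e-5
      s2 <- st; s2$params[[nm]]$W[i] <- s2$params[[nm]]$W[i] + eps
      s3 <- st; s3$params[[nm]]$W[i] <- s3$params[[nm]]$W[i] - eps
      num <- (lossOf(s2) - lossOf(s3)) / (2 * eps)
      expect_equal(gr[[nm]]$W[i], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("tiny overfit training collapses the hole loss and resumes bitwise", {
  fix <- tinyOverfitFixture()
  L <- fix$res$log$L_hole
  expect_equal(nrow(fix$res$log), 300)
  expect_true(all(is.finite(L)))
  drop <- 1 - mean(tail(L, 10)) / L[1]
  expect_gte(drop, 0.9)

  # resume from the mid-run checkpoint: remaining log reproduced bitwise
  ck <- file.path(fix$ckdir, "ckpt_000150.rds")
  expect_true(file.exists(ck))
  res2 <- trainInpainter(list(list(clip = fix$syn$clean,
                                   masks = fix$syn$masks)),
                         initGenerator(fix$cfg, seed = 7), fix$sched,
                         weights = lossWeights(lambdaAdv = 0),
                         resumeFrom = ck)
  expect_identical(res2$log[151:300, ], fix$res$log[151:300, ])
})

test_that("adversarial training updates both networks with finite losses", {
  syn <- generateClip(syntheticSceneSpec(frameCount = 6,
                                         frameSize = c(64, 64), seed = 31))
  cfg <- tinyTransformerConfig()
  st <- initGenerator(cfg, seed = 2)
  ds <- initDiscriminator(cfg, seed = 3)
  sched <- trainSchedule("finetune", iterations = 3, batchSize = 1,
                         lr = 1e-3, seed = 9)
  res <- trainInpainter(list(list(clip = syn$clean, masks = syn$masks)),
                        st, sched, weights = lossWeights(lambdaAdv = 0.01),
                        discState = ds)
  expect_true(all(is.finite(as.matrix(res$log[, 3:7]))))
  expect_true(any(res$log$L_D != 0))
  expect_false(identical(res$discState$params$d1$W, ds$params$d1$W))
})
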