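# shared fixtures; the trained tiny model is built lazily once per test run

.fixtureCache <- new.env(parent = emptyenv())

# the desk-scale overfit clip: drifting mucosa texture, jumping highlights
overfitSceneSpec <- function() {
  syntheticSceneSpec(
    frameCount = 8, frameSize = c(64, 64),
    motion = list(driftPx = 0.8, rotDeg = 0, wobble = 0),
    highlights = list(count = 5, radiusRange = c(3, 6), saturation = 1,
                      ringWidth = 1, ringDarken = 0.55, jumpProb = 0.5,
                      visibleProb = 0.85),
    seed = 21)
}

# train the tiny generator once (300 iterations, pure L1) and cache it
tinyOverfitFixture <- function() {
  fix <- .fixtureCache$overfit
  if (!is.null(fix)) return(fix)
  spec <- overfitSceneSpec()
  syn <- generateClip(spec)
  cfg <- tinyTransformerConfig()
  st0 <- initGenerator(cfg, seed = 7)
  ckdir <- file.path(tempdir(), "specfill_ckpt")
  dir.create(ckdir, showWarnings = FALSE)
  sched <- trainSchedule("init", iterations = 300, batchSize = 1, lr = 3e-3,
                         beta1 = 0.5, checkpointEvery = 150, seed = 123)
  res <- trainInpainter(list(list(clip = syn$clean, masks = syn$masks)),
                        st0, sched, weights = lossWeights(lambdaAdv = 0),
                        checkpointDir = ckdir)
  fix <- list(spec = spec, syn = syn, cfg = cfg, sched = sched, res = res,
              ckdir = ckdir)
  .fixtureCache$overfit <- fix
  fix
}
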