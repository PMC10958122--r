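#' Training schedule
#'
#' Describes one training phase.  Phase \code{"init"} is the initialisation
#' phase on smoothly-moving random Bezier masks; phase \code{"finetune"}
#' continues from an initialised model on translated pseudo-ground-truth
#' specularity masks (the transfer-learning recipe).
#'
#' @param phase \code{"init"} or \code{"finetune"}.
#' @param iterations number of optimisation iterations (>= 1).
#' @param batchSize windows per iteration (gradients are averaged).
#' @param lr Adam learning rate (generator and discriminator).
#' @param beta1,beta2 Adam moment decay rates.
#' @param checkpointEvery write a checkpoint every this many iterations
#'   (Inf = only on request).
#' @param seed master seed; fans out to data sampling and updates.
#' @export
trainSchedule <- function(phase = c("init", "finetune"), iterations = 300,
                          batchSize = 2, lr = 1e-4, beta1 = 0, beta2 = 0.99,
                          checkpointEvery = Inf, seed = 1L) {
  phase <- match.arg(phase)
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(phase = phase, iterations = as.integer(iterations),
                 batchSize = as.integer(batchSize), lr = lr,
                 beta1 = beta1, beta2 = beta2,
                 checkpointEvery = checkpointEvery, seed = as.integer(seed)),
            class = "TrainSchedule")
}

#' Save a training checkpoint
#'
#' The checkpoint stores the generator and discriminator parameters, Adam
#' state, configuration, loss log, master seed and current RNG state, so a
#' resumed run reproduces the remaining loss log bitwise.
#'
#' @param ckpt checkpoint list (as produced inside
#'   \code{\link{trainInpainter}}).
#' @param path destination file.
#' @export
saveCheckpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' Load a training checkpoint
#' @param path checkpoint file written by \code{\link{saveCheckpoint}}.
#' @export
loadCheckpoint <- function(path) readRDS(path)

#' Train the inpainting generator (optionally adversarially)
#'
#' Alternating generator/discriminator optimisation of the combined L1 +
#' adversarial objective with hinge discriminator loss.  Each iteration
#' samples a clip and a target frame, builds the conditioning window
#' (neighbours plus distant frames), runs the generator, and applies one
#' Adam step; with a discriminator present and \code{lambdaAdv > 0} the
#' discriminator is updated on the composited output first (1:1 ratio).
#'
#' @param data list of training examples, each a list with elements
#'   \code{clip} (\linkS4class{VideoClip}) and \code{masks}
#'   (\linkS4class{MaskSequence}).
#' @param state a \code{GeneratorState} (from \code{\link{initGenerator}}).
#' @param schedule a \code{\link{trainSchedule}}.
#' @param weights a \code{\link{lossWeights}} list.
#' @param discState optional \code{DiscriminatorState}; required when
#'   \code{weights$lambdaAdv > 0}.
#' @param checkpointDir optional directory for periodic checkpoints.
#' @param resumeFrom optional checkpoint (path or list) to resume from; the
#'   remaining iterations reproduce an uninterrupted run bitwise.
#' @return list with \code{state}, \code{discState}, \code{log} (one row
#'   per iteration: iteration, phase, L_hole, L_valid, L_adv, L_D, L_total)
#'   and \code{checkpoint} (the final checkpoint list).
#' @export
trainInpainter <- function(data, state, schedule, weights = lossWeights(),
                           discState = NULL, checkpointDir = NULL,
                           resumeFrom = NULL) {
  useAdv <- weights$lambdaAdv > 0
  if (useAdv && is.null(discState))
    stop("lambdaAdv > 0 requires a discriminator state")
  if (!is.null(resumeFrom)) {
    ck <- if (is.character(resumeFrom)) loadCheckpoint(resumeFrom) else resumeFrom
    state <- ck$state; discState <- ck$discState
    opt <- ck$opt; dopt <- ck$dopt
    log <- ck$log; startIter <- ck$iteration
    assign(".Random.seed", ck$rngState, envir = globalenv())
  } else {
    opt <- adamInit(state$params)
    dopt <- if (!is.null(discState)) adamInit(discState$params) else NULL
    log <- NULL; startIter <- 0L
    set.seed(schedule$seed)
  }
  n <- state$config$neighbor; s <- state$config$distantStride
  for (it in (startIter + 1):schedule$iterations) {
    gradsTot <- NULL
    Lh <- Lv <- La <- LD <- 0
    for (b in seq_len(schedule$batchSize)) {
      ex <- data[[sample.int(length(data), 1)]]
      Yall <- frames(ex$clip); Mall <- masks(ex$masks)
      T <- dim(Yall)[4]
      t <- sample.int(T, 1)
      win <- sampleTrainingWindow(T, t, n, s)
      Yw <- Yall[, , , win, drop = FALSE]
      Mw <- Mall[, , win, drop = FALSE]
      fw <- generatorForward(state, Yw, Mw, train = TRUE)
      lh <- lossHole(Yw, fw$Yhat, Mw)
      lv <- lossValid(Yw, fw$Yhat, Mw)
      if (!is.finite(lh) || !is.finite(lv))
        stop(sprintf("non-finite loss at iteration %d (L_hole=%g, L_valid=%g)",
                     it, lh, lv))
      dYhat <- lossL1Grad(Yw, fw$Yhat, Mw, weights)
      la <- 0; ld <- 0
      if (useAdv) {
        d <- dim(Yw)
        Mrep <- aperm(array(Mw, c(d[1], d[2], d[4], 3)), c(1, 2, 4, 3))
        comp <- Yw * (1 - Mrep) + fw$Yhat * Mrep
        # discriminator update (fake detached)
        dr <- discForward(2 * Yw - 1, discState$params)
        df <- discForward(2 * comp - 1, discState$params)
        ld <- lossDiscriminator(dr$out, df$out)
        dReal <- -(dr$out < 1) / length(dr$out)
        dFake <- (df$out > -1) / length(df$out)
        gb <- discBackward(array(dReal, dim(dr$out)), discState$params,
                           dr$cache)
        gf <- discBackward(array(dFake, dim(df$out)), discState$params,
                           df$cache)
        dg <- gb$grads
        for (nm in names(gf$grads)) dg <- gradAcc(dg, nm, gf$grads[[nm]])
        up <- adamStep(discState$params, dg, dopt, lr = schedule$lr,
                       beta1 = schedule$beta1, beta2 = schedule$beta2)
        discState$params <- up$params; dopt <- up$opt
        # generator adversarial gradient through the updated discriminator
        df2 <- discForward(2 * comp - 1, discState$params)
        la <- lossAdv(df2$out)
        dscore <- array(-1 / length(df2$out), dim(df2$out))
        bb <- discBackward(dscore, discState$params, df2$cache)
        dYhat <- dYhat + weights$lambdaAdv * 2 * Mrep * bb$dx
      }
      grads <- generatorBackward(state, fw$cache, dYhat)
      if (is.null(gradsTot)) gradsTot <- grads
      else for (nm in names(grads)) gradsTot <- gradAcc(gradsTot, nm,
                                                        grads[[nm]])
      Lh <- Lh + lh; Lv <- Lv + lv; La <- La + la; LD <- LD + ld
    }
    bs <- schedule$batchSize
    for (nm in names(gradsTot)) for (wn in names(gradsTot[[nm]]))
      gradsTot[[nm]][[wn]] <- gradsTot[[nm]][[wn]] / bs
    up <- adamStep(state$params, gradsTot, opt, lr = schedule$lr,
                   beta1 = schedule$beta1, beta2 = schedule$beta2)
    state$params <- up$params; opt <- up$opt
    Lh <- Lh / bs; Lv <- Lv / bs; La <- La / bs; LD <- LD / bs
    row <- data.frame(iteration = it, phase = schedule$phase,
                      L_hole = Lh, L_valid = Lv, L_adv = La, L_D = LD,
                      L_total = weights$lambdaHole * Lh +
                        weights$lambdaValid * Lv + weights$lambdaAdv * La)
    log <- rbind(log, row)
    if (!is.null(checkpointDir) && is.finite(schedule$checkpointEvery) &&
        it %% schedule$checkpointEvery == 0) {
      ck <- makeCheckpoint(state, discState, opt, dopt, it, log, schedule)
      saveCheckpoint(ck, file.path(checkpointDir,
                                   sprintf("ckpt_%06d.rds", it)))
    }
  }
  ck <- makeCheckpoint(state, discState, opt, dopt, schedule$iterations, log,
                       schedule)
  list(state = state, discState = discState, log = log, checkpoint = ck)
}

makeCheckpoint <- function(state, discState, opt, dopt, iteration, log,
                           schedule) {
  list(state = state, discState = discState, opt = opt, dopt = dopt,
       iteration = iteration, log = log, schedule = schedule,
       rngState = get(".Random.seed", envir = globalenv()))
}
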