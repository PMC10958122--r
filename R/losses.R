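#' Loss weights for the inpainting objective
#'
#' @param lambdaHole,lambdaValid,lambdaAdv nonnegative weights of the hole
#'   L1 term, the valid-region L1 term, and the adversarial term.  The
#'   defaults (1, 1, 0.01) are the standard empirical choice for this
#'   architecture family.
#' @export
lossWeights <- function(lambdaHole = 1, lambdaValid = 1, lambdaAdv = 0.01) {
  if (any(c(lambdaHole, lambdaValid, lambdaAdv) < 0))
    stop("loss weights must be >= 0")
  list(lambdaHole = lambdaHole, lambdaValid = lambdaValid,
       lambdaAdv = lambdaAdv)
}

# replicate (H, W, T) masks over the channel axis of (H, W, C, T) arrays
maskRep <- function(M, d) {
  if (length(dim(M)) == 2L) dim(M) <- c(dim(M), 1L)
  aperm(array(M, c(dim(M)[1], dim(M)[2], dim(M)[3], d[3])), c(1, 2, 4, 3))
}

#' Hole reconstruction loss
#'
#' Mean absolute error over hole pixels (all channels):
#' \code{||M (Y - Yhat)||_1 / ||M||_1}.
#'
#' @param Y,Yhat original and generated frame arrays \code{(H, W, C, T)}
#'   (or \code{(H, W)} / \code{(H, W, C)}; shapes are promoted).
#' @param M hole masks \code{(H, W, T)} (1 = hole).
#' @export
lossHole <- function(Y, Yhat, M) {
  Y <- promote4d(Y); Yhat <- promote4d(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("shape mismatch")
  nM <- sum(M)
  if (nM == 0) stop("all-zero mask: hole loss undefined")
  Mr <- maskRep(M, dim(Y))
  sum(abs(Mr * (Y - Yhat))) / sum(Mr)
}

#' Valid-region reconstruction loss
#'
#' Mirror of \code{\link{lossHole}} over the valid region \code{1 - M}.
#' @inheritParams lossHole
#' @export
lossValid <- function(Y, Yhat, M) {
  Y <- promote4d(Y); Yhat <- promote4d(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("shape mismatch")
  if (all(M == 1)) stop("all-one mask: valid loss undefined")
  Mr <- 1 - maskRep(M, dim(Y))
  sum(abs(Mr * (Y - Yhat))) / sum(Mr)
}

promote4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("inputs must be arrays")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Adversarial (generator) loss
#'
#' \code{-mean(D(z))} over all entries of the discriminator score map of
#' the generated clip.
#'
#' @param fakeScores discriminator score map of generated frames.
#' @export
lossAdv <- function(fakeScores) {
  if (length(fakeScores) == 0) stop("empty score map")
  -mean(fakeScores)
}

#' Total generator objective
#'
#' \code{lambdaHole * Lhole + lambdaValid * Lvalid + lambdaAdv * Ladv}.
#'
#' @inheritParams lossHole
#' @param fakeScores discriminator scores of the generated clip (may be
#'   NULL when \code{lambdaAdv} is 0).
#' @param w a \code{\link{lossWeights}} list.
#' @export
lossTotal <- function(Y, Yhat, M, fakeScores = NULL, w = lossWeights()) {
  la <- if (w$lambdaAdv > 0 || !is.null(fakeScores))
    lossAdv(fakeScores %||% 0) else 0
  w$lambdaHole * lossHole(Y, Yhat, M) +
    w$lambdaValid * lossValid(Y, Yhat, M) +
    w$lambdaAdv * la
}

#' Hinge discriminator loss
#'
#' \code{mean(ReLU(1 - D(real))) + mean(ReLU(1 + D(fake)))}.
#'
#' @param realScores,fakeScores discriminator score maps of real and
#'   generated clips.
#' @export
lossDiscriminator <- function(realScores, fakeScores) {
  if (length(realScores) == 0 || length(fakeScores) == 0)
    stop("empty score map")
  mean(pmax(1 - realScores, 0)) + mean(pmax(1 + fakeScores, 0))
}

#' Frame index set conditioning a target frame
#'
#' Neighbours \code{t - n ... t + n} clamped to the clip, united with
#' distant frames sampled uniformly at stride \code{s} starting at frame 1,
#' deduplicated and sorted.  Frames are 1-based.
#'
#' @param T clip length.
#' @param t target frame (1-based, in \code{[1, T]}).
#' @param n neighbour radius.
#' @param s distant sampling stride.
#' @return sorted integer vector of frame indices.
#' @export
sampleTrainingWindow <- function(T, t, n, s) {
  if (t < 1 || t > T) stop("target frame outside clip")
  nb <- max(1, t - n):min(T, t + n)
  sort(unique(c(nb, seq(1, T, by = s))))
}

# analytic gradient of the weighted L1 terms w.r.t. Yhat (subgradient 0 at
# exact ties); adversarial gradient handled by discriminator backprop
lossL1Grad <- function(Y, Yhat, M, w) {
  d <- dim(Y)
  Mr <- maskRep(M, d)
  sgn <- sign(Yhat - Y)
  w$lambdaHole * Mr * sgn / sum(Mr) +
    w$lambdaValid * (1 - Mr) * sgn / sum(1 - Mr)
}
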