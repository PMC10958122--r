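#' Configuration of the spatial-temporal transformer generator
#'
#' The generator is a frame-level convolutional encoder (two stride-2
#' convolutions, downsampling by 4), a stack of multi-head spatial-temporal
#' attention layers operating on patches of the feature maps, and a
#' convolutional decoder with nearest-neighbour upsampling back to the
#' input size.  Heads attend at different patch scales so that coarse
#' structure and fine detail can both be borrowed from valid regions of
#' neighbouring and distant frames.
#'
#' @param inputSize frame size (H, W); both must be divisible by 4.
#' @param channels transformer feature width C (divisible by the number of
#'   heads).
#' @param layers number of attention layers (8 is the full-scale default).
#' @param heads list of patch sizes \code{c(r1, r2)}; each must divide the
#'   feature-map size \code{inputSize / 4} exactly.
#' @param neighbor n, number of neighbouring frames attended on each side.
#' @param distantStride s, stride of the uniformly sampled distant frames.
#' @param encChannels widths of the three intermediate encoder/decoder
#'   convolutions.
#' @param discChannels width of the first spatio-temporal discriminator
#'   convolution.
#' @return a validated list of class \code{TransformerConfig}.
#' @export
transformerConfig <- function(inputSize = c(288, 288), channels = 256,
                              layers = 8,
                              heads = list(c(72, 72), c(36, 36),
                                           c(18, 18), c(9, 9)),
                              neighbor = 2, distantStride = 10,
                              encChannels = c(64, 64, 128),
                              discChannels = 64) {
  if (layers < 1) stop("layers must be >= 1")
  if (neighbor < 0) stop("neighbor must be >= 0")
  if (distantStride < 1) stop("distantStride must be >= 1")
  if (any(inputSize %% 4 != 0)) stop("inputSize must be divisible by 4")
  featureSize <- inputSize %/% 4L
  for (hd in heads)
    if (any(featureSize %% hd != 0))
      stop(sprintf("head patch size (%d, %d) must divide the feature map (%d, %d)",
                   hd[1], hd[2], featureSize[1], featureSize[2]))
  if (channels %% length(heads) != 0)
    stop("channels must be divisible by the number of heads")
  structure(list(inputSize = as.integer(inputSize),
                 channels = as.integer(channels), layers = as.integer(layers),
                 heads = heads, neighbor = as.integer(neighbor),
                 distantStride = as.integer(distantStride),
                 encChannels = as.integer(encChannels),
                 discChannels = as.integer(discChannels),
                 featureSize = featureSize, downsample = 4L),
            class = "TransformerConfig")
}

#' Desk-scale transformer configuration
#'
#' A small configuration (64 x 64 frames, 32 channels, 1 layer, two heads)
#' used for tests, examples and CPU-scale training demonstrations.
#'
#' @param inputSize frame size, default \code{c(64, 64)}.
#' @param layers number of attention layers.
#' @export
tinyTransformerConfig <- function(inputSize = c(64, 64), layers = 1) {
  transformerConfig(inputSize = inputSize, channels = 32, layers = layers,
                    heads = list(c(8, 8), c(4, 4)),
                    neighbor = 2, distantStride = 10,
                    encChannels = c(16, 16, 24), discChannels = 16)
}

# patch extract/fold permutation for an (h, w, cg, T) block and (r1, r2)
patchPerm <- function(h, w, cg, T, r1, r2) {
  key <- paste("pp", h, w, cg, T, r1, r2, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  np <- (h %/% r1) * (w %/% r2)
  d <- r1 * r2 * cg
  N <- np * T
  i <- rep(seq_len(h), times = w * cg * T)
  j <- rep(rep(seq_len(w), each = h), times = cg * T)
  ch <- rep(rep(seq_len(cg), each = h * w), times = T)
  t <- rep(seq_len(T), each = h * w * cg)
  pi <- (i - 1) %/% r1; di <- i - pi * r1
  pj <- (j - 1) %/% r2; dj <- j - pj * r2
  p <- pj * (h %/% r1) + pi + 1
  col <- (ch - 1) * r1 * r2 + (dj - 1) * r1 + di
  row <- (t - 1) * np + p
  perm <- (col - 1) * N + row
  res <- list(perm = perm, N = N, d = d, np = np)
  .idxCache[[key]] <- res
  res
}

extractPatches <- function(x, r1, r2) {
  dm <- dim(x)
  pp <- patchPerm(dm[1], dm[2], dm[3], dm[4], r1, r2)
  M <- numeric(pp$N * pp$d)
  M[pp$perm] <- x
  dim(M) <- c(pp$N, pp$d)
  M
}

foldPatches <- function(M, h, w, cg, T, r1, r2) {
  pp <- patchPerm(h, w, cg, T, r1, r2)
  array(M[pp$perm], c(h, w, cg, T))
}

# block maximum downsampling of an (H, W) or (H, W, T) mask by factor f
blockMax <- function(m, f) {
  if (length(dim(m)) == 2L) dim(m) <- c(dim(m), 1L)
  d <- dim(m)
  h <- d[1] %/% f; w <- d[2] %/% f
  dim(m) <- c(f, h, f, w, d[3])
  out <- apply(m, c(2, 4, 5), max)
  out
}

#' Similarity between two flattened feature patches
#'
#' The normalised dot product \code{sum(pq * pk) / (r1 * r2 * c)} used in
#' the matching stage of the transformer.
#'
#' @param pq,pk flattened query and key patch vectors of length
#'   \code{r1 * r2 * c}.
#' @param r1,r2 patch height and width; \code{c} channels per head.
#' @param c channels per head.
#' @export
patchSimilarity <- function(pq, pk, r1, r2, c) {
  if (length(pq) != length(pk)) stop("patch vectors differ in length")
  if (length(pq) != r1 * r2 * c) stop("patch length must equal r1*r2*c")
  sum(pq * pk) / (r1 * r2 * c)
}

#' Attention weights for one query over all patches
#'
#' Softmax of the similarity row over \emph{valid} patches only (patches
#' intersecting the hole region are excluded from both the numerator and
#' the denominator and receive weight exactly 0).  If no patch is valid the
#' row is all-zero and flagged degenerate.  Numerically stabilised by
#' max-subtraction.
#'
#' @param sim numeric similarity row.
#' @param valid logical vector marking valid (unoccluded) patches.
#' @return list with \code{weights} and logical \code{degenerate}.
#' @export
attentionWeights <- function(sim, valid) {
  if (any(is.nan(sim))) stop("NaN similarity")
  if (length(sim) != length(valid)) stop("length mismatch")
  w <- numeric(length(sim))
  if (!any(valid)) return(list(weights = w, degenerate = TRUE))
  s <- sim[valid]
  e <- exp(s - max(s))
  w[valid] <- e / sum(e)
  list(weights = w, degenerate = FALSE)
}

#' Attend: weighted sum of value patches
#'
#' @param weights attention weight row (length N).
#' @param values N x d matrix of flattened value patches.
#' @return the output patch (length d).
#' @export
attend <- function(weights, values) {
  if (length(weights) != nrow(values)) stop("length mismatch")
  as.numeric(crossprod(values, weights))
}

# vectorised masked softmax over rows of S; invalid columns get exactly 0
maskedSoftmax <- function(S, valid) {
  if (any(is.nan(S))) stop("NaN similarity in attention")
  N <- nrow(S)
  A <- matrix(0, N, ncol(S))
  if (!any(valid)) return(list(A = A, degenerate = rep(TRUE, N)))
  Sv <- S[, valid, drop = FALSE]
  m <- apply(Sv, 1, max)
  E <- exp(Sv - m)
  rs <- rowSums(E)
  A[, valid] <- E / rs
  list(A = A, degenerate = rep(FALSE, N))
}

#' Initialise the generator
#'
#' Builds all encoder, attention-layer and decoder weights from a seed.
#'
#' @param config a \code{\link{transformerConfig}}.
#' @param seed integer weight-initialisation seed.
#' @return a \code{GeneratorState} list with \code{params}, \code{config}
#'   and \code{seed}.
#' @export
initGenerator <- function(config, seed = 1L) {
  e <- config$encChannels; C <- config$channels
  withSeed(seed, {
    p <- list(
      enc1 = conv2dInit(3, e[1], 3),
      enc2 = conv2dInit(e[1], e[2], 3),
      enc3 = conv2dInit(e[2], e[3], 3),
      enc4 = conv2dInit(e[3], C, 3),
      dec1 = conv2dInit(C, e[3], 3),
      dec2 = conv2dInit(e[3], e[1], 3),
      dec3 = conv2dInit(e[1], 3, 3, gain = 1))
    for (l in seq_len(config$layers)) {
      p[[sprintf("l%d.Wq", l)]] <- conv1x1Init(C, C)
      p[[sprintf("l%d.Wk", l)]] <- conv1x1Init(C, C)
      p[[sprintf("l%d.Wv", l)]] <- conv1x1Init(C, C)
      p[[sprintf("l%d.Wo", l)]] <- conv1x1Init(C, C)
      p[[sprintf("l%d.ffn1", l)]] <- conv2dInit(C, C, 3)
      p[[sprintf("l%d.ffn2", l)]] <- conv2dInit(C, C, 3, gain = 1)
    }
    structure(list(params = p, config = config, seed = as.integer(seed)),
              class = "GeneratorState")
  })
}

#' @export
print.GeneratorState <- function(x, ...) {
  n <- sum(vapply(x$params, function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("GeneratorState: %d layers, %d channels, %s parameters (seed %d)\n",
              x$config$layers, x$config$channels, format(n, big.mark = ","),
              x$seed))
  invisible(x)
}

#' Encode masked frames to feature maps
#'
#' Frame-level encoder: each frame is processed independently (no
#' cross-frame coupling), producing feature maps of size
#' \code{inputSize / 4}.
#'
#' @param maskedFrames \code{(H, W, 3, T)} array of pre-masked frames in
#'   \code{[-1, 1]} (holes zeroed).
#' @param masks \code{(H, W, T)} binary mask array (only checked for shape).
#' @param state a \code{GeneratorState}.
#' @return feature array \code{(h, w, C, T)}.
#' @export
encodeFrames <- function(maskedFrames, masks, state) {
  d <- dim(maskedFrames)
  if (!all(dim(masks) == d[c(1, 2, 4)]))
    stop("frame/mask size mismatch")
  encoderForward(maskedFrames, state$params)$out
}

encoderForward <- function(x, p) {
  c1 <- conv2dForward(x, p$enc1, 3, 1); a1 <- lreluForward(c1$out)
  c2 <- conv2dForward(a1$out, p$enc2, 3, 2); a2 <- lreluForward(c2$out)
  c3 <- conv2dForward(a2$out, p$enc3, 3, 1); a3 <- lreluForward(c3$out)
  c4 <- conv2dForward(a3$out, p$enc4, 3, 2); a4 <- lreluForward(c4$out)
  list(out = a4$out, cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2,
                                  c3 = c3, a3 = a3, c4 = c4, a4 = a4))
}

encoderBackward <- function(dout, p, cache, grads) {
  d <- lreluBackward(dout, cache$a4$cache)
  b <- conv2dBackward(d, p$enc4, cache$c4$cache)
  grads <- gradAcc(grads, "enc4", b$grads)
  d <- lreluBackward(b$dx, cache$a3$cache)
  b <- conv2dBackward(d, p$enc3, cache$c3$cache)
  grads <- gradAcc(grads, "enc3", b$grads)
  d <- lreluBackward(b$dx, cache$a2$cache)
  b <- conv2dBackward(d, p$enc2, cache$c2$cache)
  grads <- gradAcc(grads, "enc2", b$grads)
  d <- lreluBackward(b$dx, cache$a1$cache)
  b <- conv2dBackward(d, p$enc1, cache$c1$cache)
  grads <- gradAcc(grads, "enc1", b$grads)
  list(dx = b$dx, grads = grads)
}

# one attention layer forward on features f (h, w, C, T)
attnLayerForward <- function(f, p, l, config, validList) {
  dm <- dim(f)
  h <- dm[1]; w <- dm[2]; C <- dm[3]; T <- dm[4]
  nh <- length(config$heads); cg <- C %/% nh
  qf <- conv1x1Forward(f, p[[sprintf("l%d.Wq", l)]])
  kf <- conv1x1Forward(f, p[[sprintf("l%d.Wk", l)]])
  vf <- conv1x1Forward(f, p[[sprintf("l%d.Wv", l)]])
  att <- array(0, c(h, w, C, T))
  headCache <- vector("list", nh)
  for (g in seq_len(nh)) {
    r1 <- config$heads[[g]][1]; r2 <- config$heads[[g]][2]
    idx <- ((g - 1) * cg + 1):(g * cg)
    Q <- extractPatches(qf$out[, , idx, , drop = FALSE], r1, r2)
    K <- extractPatches(kf$out[, , idx, , drop = FALSE], r1, r2)
    V <- extractPatches(vf$out[, , idx, , drop = FALSE], r1, r2)
    dval <- r1 * r2 * cg
    S <- tcrossprod(Q, K) / dval
    ms <- maskedSoftmax(S, validList[[g]])
    O <- ms$A %*% V
    att[, , idx, ] <- foldPatches(O, h, w, cg, T, r1, r2)
    headCache[[g]] <- list(Q = Q, K = K, V = V, A = ms$A, d = dval,
                           r1 = r1, r2 = r2, idx = idx,
                           degenerate = ms$degenerate)
  }
  of <- conv1x1Forward(att, p[[sprintf("l%d.Wo", l)]])
  f2 <- f + of$out
  g1 <- conv2dForward(f2, p[[sprintf("l%d.ffn1", l)]], 3, 1)
  ga <- lreluForward(g1$out)
  g2 <- conv2dForward(ga$out, p[[sprintf("l%d.ffn2", l)]], 3, 1)
  f3 <- f2 + g2$out
  list(out = f3,
       cache = list(qf = qf, kf = kf, vf = vf, heads = headCache, of = of,
                    g1 = g1, ga = ga, g2 = g2, dimF = dm))
}

attnLayerBackward <- function(dout, p, l, config, cache, grads) {
  dm <- cache$dimF
  h <- dm[1]; w <- dm[2]; C <- dm[3]; T <- dm[4]
  nh <- length(config$heads); cg <- C %/% nh
  # ffn residual
  b2 <- conv2dBackward(dout, p[[sprintf("l%d.ffn2", l)]], cache$g2$cache)
  grads <- gradAcc(grads, sprintf("l%d.ffn2", l), b2$grads)
  dga <- lreluBackward(b2$dx, cache$ga$cache)
  b1 <- conv2dBackward(dga, p[[sprintf("l%d.ffn1", l)]], cache$g1$cache)
  grads <- gradAcc(grads, sprintf("l%d.ffn1", l), b1$grads)
  df2 <- dout + b1$dx
  # fusion residual
  bo <- conv1x1Backward(df2, p[[sprintf("l%d.Wo", l)]], cache$of$cache)
  grads <- gradAcc(grads, sprintf("l%d.Wo", l), bo$grads)
  datt <- bo$dx
  dq <- array(0, c(h, w, C, T)); dk <- dq; dv <- dq
  for (g in seq_len(nh)) {
    hc <- cache$heads[[g]]
    dO <- extractPatches(datt[, , hc$idx, , drop = FALSE], hc$r1, hc$r2)
    dA <- tcrossprod(dO, hc$V)
    dV <- crossprod(hc$A, dO)
    dS <- hc$A * (dA - rowSums(hc$A * dA))
    dQ <- dS %*% hc$K / hc$d
    dK <- crossprod(dS, hc$Q) / hc$d
    dq[, , hc$idx, ] <- foldPatches(dQ, h, w, cg, T, hc$r1, hc$r2)
    dk[, , hc$idx, ] <- foldPatches(dK, h, w, cg, T, hc$r1, hc$r2)
    dv[, , hc$idx, ] <- foldPatches(dV, h, w, cg, T, hc$r1, hc$r2)
  }
  bq <- conv1x1Backward(dq, p[[sprintf("l%d.Wq", l)]], cache$qf$cache)
  grads <- gradAcc(grads, sprintf("l%d.Wq", l), bq$grads)
  bk <- conv1x1Backward(dk, p[[sprintf("l%d.Wk", l)]], cache$kf$cache)
  grads <- gradAcc(grads, sprintf("l%d.Wk", l), bk$grads)
  bv <- conv1x1Backward(dv, p[[sprintf("l%d.Wv", l)]], cache$vf$cache)
  grads <- gradAcc(grads, sprintf("l%d.Wv", l), bv$grads)
  list(dx = df2 + bq$dx + bk$dx + bv$dx, grads = grads)
}

# per-head patch validity from pixel masks: a patch is invalid iff it
# intersects the hole region at feature scale
patchValidity <- function(maskArr, config) {
  mf <- blockMax(maskArr, config$downsample) # (h, w, T)
  h <- dim(mf)[1]; w <- dim(mf)[2]; T <- dim(mf)[3]
  lapply(config$heads, function(hd) {
    mfa <- array(mf, c(h, w, 1, T))
    hole <- extractPatches(mfa, hd[1], hd[2])
    rowSums(hole) == 0
  })
}

#' Run the spatial-temporal transformer on encoded features
#'
#' Applies \code{layers} attention layers (embed, patch matching,
#' attention, attending, fold, head concatenation, residual fusion and a
#' convolutional feed-forward block) to the feature maps.
#'
#' @param features \code{(h, w, C, T)} feature array from
#'   \code{\link{encodeFrames}}.
#' @param maskArr \code{(H, W, T)} pixel-level hole masks.
#' @param state a \code{GeneratorState}.
#' @param returnAttention if TRUE, also return the per-layer per-head
#'   attention matrices and validity flags.
#' @return fused features, or a list \code{(features, attention, validity)}.
#' @export
transformerForward <- function(features, maskArr, state,
                               returnAttention = FALSE) {
  config <- state$config
  validList <- patchValidity(maskArr, config)
  f <- features
  attn <- list()
  for (l in seq_len(config$layers)) {
    fw <- attnLayerForward(f, state$params, l, config, validList)
    f <- fw$out
    if (returnAttention)
      attn[[l]] <- lapply(fw$cache$heads, function(hc)
        list(A = hc$A, degenerate = hc$degenerate))
  }
  if (returnAttention)
    list(features = f, attention = attn, validity = validList)
  else f
}

decoderForward <- function(f, p) {
  d1 <- conv2dForward(f, p$dec1, 3, 1); a1 <- lreluForward(d1$out)
  u1 <- upsample2Forward(a1$out)
  d2 <- conv2dForward(u1$out, p$dec2, 3, 1); a2 <- lreluForward(d2$out)
  u2 <- upsample2Forward(a2$out)
  d3 <- conv2dForward(u2$out, p$dec3, 3, 1)
  th <- tanhForward(d3$out)
  list(out = th$out, cache = list(d1 = d1, a1 = a1, u1 = u1, d2 = d2,
                                  a2 = a2, u2 = u2, d3 = d3, th = th))
}

decoderBackward <- function(dout, p, cache, grads) {
  d <- tanhBackward(dout, cache$th$cache)
  b <- conv2dBackward(d, p$dec3, cache$d3$cache)
  grads <- gradAcc(grads, "dec3", b$grads)
  d <- upsample2Backward(b$dx, cache$u2$cache)
  d <- lreluBackward(d, cache$a2$cache)
  b <- conv2dBackward(d, p$dec2, cache$d2$cache)
  grads <- gradAcc(grads, "dec2", b$grads)
  d <- upsample2Backward(b$dx, cache$u1$cache)
  d <- lreluBackward(d, cache$a1$cache)
  b <- conv2dBackward(d, p$dec1, cache$d1$cache)
  grads <- gradAcc(grads, "dec1", b$grads)
  list(dx = b$dx, grads = grads)
}

# full generator forward on a window: Y (H, W, 3, Tw) in [0,1], M (H, W, Tw)
generatorForward <- function(state, Y, M, train = FALSE) {
  d <- dim(Y)
  Mrep <- aperm(array(M, c(d[1], d[2], d[4], 3)), c(1, 2, 4, 3))
  x <- (2 * Y - 1) * (1 - Mrep)
  enc <- encoderForward(x, state$params)
  config <- state$config
  validList <- patchValidity(M, config)
  f <- enc$out
  layerCaches <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    fw <- attnLayerForward(f, state$params, l, config, validList)
    f <- fw$out
    if (train) layerCaches[[l]] <- fw$cache
  }
  dec <- decoderForward(f, state$params)
  Yhat <- (dec$out + 1) / 2
  if (!train) return(list(Yhat = Yhat))
  list(Yhat = Yhat,
       cache = list(enc = enc$cache, layers = layerCaches, dec = dec$cache,
                    validList = validList))
}

# backward from dL/dYhat; returns gradient list matching state$params
generatorBackward <- function(state, cache, dYhat) {
  grads <- list()
  d <- dYhat / 2 # Yhat = (tanh + 1)/2
  db <- decoderBackward(d, state$params, cache$dec, grads)
  grads <- db$grads
  dx <- db$dx
  config <- state$config
  for (l in rev(seq_len(config$layers))) {
    ab <- attnLayerBackward(dx, state$params, l, config, cache$layers[[l]],
                            grads)
    grads <- ab$grads
    dx <- ab$dx
  }
  eb <- encoderBackward(dx, state$params, cache$enc, grads)
  eb$grads
}

#' Inpaint a clip with the transformer generator
#'
#' Processes the clip in windows: each group of \code{2n + 1} consecutive
#' target frames is conditioned on itself plus distant frames sampled at
#' stride \code{s} across the whole clip.  By default the output is
#' composited with the input so that valid (mask-0) pixels pass through
#' bit-exact: \code{Yfinal = X (1 - M) + Yhat M}.
#'
#' @param clip a \linkS4class{VideoClip}.
#' @param maskSeq a \linkS4class{MaskSequence} aligned with the clip.
#' @param state a \code{GeneratorState}.
#' @param temporal if FALSE every frame is processed alone (single-frame
#'   windows, the no-temporal ablation).
#' @param composite if TRUE (default) valid pixels are copied from the
#'   input.
#' @return an inpainted \linkS4class{VideoClip}.
#' @export
inpaintClip <- function(clip, maskSeq, state, temporal = TRUE,
                        composite = TRUE) {
  Y <- frames(clip); M <- masks(maskSeq)
  T <- nFrames(clip)
  if (!all(frameSize(clip) == frameSize(maskSeq)) || T != nFrames(maskSeq))
    stop("clip/mask size mismatch")
  config <- state$config
  out <- array(0, dim(Y))
  if (!temporal) {
    for (t in seq_len(T)) {
      fw <- generatorForward(state,
                             Y[, , , t, drop = FALSE],
                             M[, , t, drop = FALSE])
      out[, , , t] <- fw$Yhat[, , , 1]
    }
  } else {
    n <- config$neighbor; s <- config$distantStride
    starts <- seq(1, T, by = 2 * n + 1)
    distant <- seq(1, T, by = s)
    for (st in starts) {
      chunk <- st:min(st + 2 * n, T)
      refs <- sort(unique(c(chunk, distant)))
      fw <- generatorForward(state,
                             Y[, , , refs, drop = FALSE],
                             M[, , refs, drop = FALSE])
      pos <- match(chunk, refs)
      out[, , , chunk] <- fw$Yhat[, , , pos]
    }
  }
  out <- clamp01(out)
  if (composite) {
    d <- dim(Y)
    Mrep <- aperm(array(M, c(d[1], d[2], d[4], 3)), c(1, 2, 4, 3))
    out <- Y * (1 - Mrep) + out * Mrep
  }
  VideoClip(out)
}

# ---- spatio-temporal patch discriminator -----------------------------------

#' Initialise the spatio-temporal patch discriminator
#'
#' A stack of three 3D convolutions (kernel 3 x 5 x 5 over time, height,
#' width; spatial stride 2) producing an unbounded real-valued score per
#' spatio-temporal patch, for use with the hinge losses.
#'
#' @param config a \code{\link{transformerConfig}} (only
#'   \code{discChannels} is used).
#' @param seed weight-initialisation seed.
#' @param zeroInit if TRUE all weights start at zero (used in tests).
#' @return a \code{DiscriminatorState} list.
#' @export
initDiscriminator <- function(config, seed = 1L, zeroInit = FALSE) {
  c0 <- config$discChannels
  withSeed(seed, {
    p <- list(d1 = conv3dInit(3, c0, 5, 5, 3),
              d2 = conv3dInit(c0, 2 * c0, 5, 5, 3),
              d3 = conv3dInit(2 * c0, 1, 5, 5, 3, gain = 1))
    if (zeroInit) p <- lapply(p, function(l) {l$W[] <- 0; l$b[] <- 0; l})
    structure(list(params = p, config = config, seed = as.integer(seed)),
              class = "DiscriminatorState")
  })
}

discForward <- function(x, p) {
  c1 <- conv3dForward(x, p$d1, 5, 5, 3, sh = 2, sw = 2, st = 1)
  a1 <- lreluForward(c1$out)
  c2 <- conv3dForward(a1$out, p$d2, 5, 5, 3, sh = 2, sw = 2, st = 1)
  a2 <- lreluForward(c2$out)
  c3 <- conv3dForward(a2$out, p$d3, 5, 5, 3, sh = 2, sw = 2, st = 1)
  list(out = c3$out, cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2,
                                  c3 = c3))
}

discBackward <- function(dout, p, cache) {
  grads <- list()
  b <- conv3dBackward(dout, p$d3, cache$c3$cache)
  grads <- gradAcc(grads, "d3", b$grads)
  d <- lreluBackward(b$dx, cache$a2$cache)
  b <- conv3dBackward(d, p$d2, cache$c2$cache)
  grads <- gradAcc(grads, "d2", b$grads)
  d <- lreluBackward(b$dx, cache$a1$cache)
  b <- conv3dBackward(d, p$d1, cache$c1$cache)
  grads <- gradAcc(grads, "d1", b$grads)
  list(dx = b$dx, grads = grads)
}

#' Score a clip with the spatio-temporal patch discriminator
#'
#' @param clip a \linkS4class{VideoClip} (or an \code{(H, W, 3, T)} array in
#'   \code{[0, 1]}).
#' @param discState a \code{DiscriminatorState}.
#' @return a \code{(T', h', w')} array of unbounded patch scores.
#' @export
discriminatorScore <- function(clip, discState) {
  x <- if (is(clip, "VideoClip")) frames(clip) else clip
  if (dim(x)[4] < 3) stop("clip shorter than the discriminator receptive depth")
  fw <- discForward(2 * x - 1, discState$params)
  sc <- fw$out # (h', w', 1, T')
  aperm(array(sc, dim(sc)[c(1, 2, 4)]), c(3, 1, 2))
}
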