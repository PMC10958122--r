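# Minimal neural-network primitives: dense-array convolutions via im2col and
# BLAS matmul, with analytic backward passes.  Arrays are (H, W, C, T) with T
# the frame/batch axis.  Index maps are cached per shape.

.idxCache <- new.env(parent = emptyenv())

im2colIndex2d <- function(H, W, C, T, k, stride, pad) {
  key <- paste("c2", H, W, C, T, k, stride, pad, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  iVec <- rep(stride * (0:(Ho - 1)), times = Wo)
  jVec <- rep(stride * (0:(Wo - 1)), each = Ho)
  base <- iVec + jVec * Hp
  di <- rep(1:k, times = k * C)
  dj <- rep(rep(1:k, each = k), times = C)
  ch <- rep(1:C, each = k * k)
  off <- di + (dj - 1) * Hp + (ch - 1) * Hp * Wp
  idx1 <- outer(base, off, "+")
  frameLen <- Hp * Wp * C
  big <- matrix(0, Ho * Wo * T, k * k * C)
  for (t in seq_len(T))
    big[((t - 1) * Ho * Wo + 1):(t * Ho * Wo), ] <- idx1 + (t - 1) * frameLen
  res <- list(idx = big, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .idxCache[[key]] <- res
  res
}

pad2d <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# parameters: list(W = (k*k*inC) x outC matrix, b = numeric(outC))
conv2dInit <- function(inC, outC, k, gain = sqrt(2)) {
  fan <- k * k * inC
  list(W = matrix(rnorm(fan * outC, 0, gain / sqrt(fan)), fan, outC),
       b = numeric(outC))
}

conv2dForward <- function(x, par, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  ix <- im2colIndex2d(d[1], d[2], d[3], d[4], k, stride, pad)
  xp <- pad2d(x, pad)
  cols <- xp[ix$idx]
  dim(cols) <- dim(ix$idx)
  out <- cols %*% par$W
  out <- sweep(out, 2, par$b, "+")
  dim(out) <- c(ix$Ho, ix$Wo, d[4], ncol(par$W))
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, cache = list(cols = cols, ix = ix, dimIn = d,
                               k = k, stride = stride, pad = pad))
}

conv2dBackward <- function(dout, par, cache) {
  dmat <- aperm(dout, c(1, 2, 4, 3))
  dim(dmat) <- c(nrow(cache$cols), ncol(par$W))
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(par$W)
  d <- cache$dimIn; ix <- cache$ix; pad <- cache$pad
  dxp <- array(0, c(ix$Hp, ix$Wp, d[3], d[4]))
  for (j in seq_len(ncol(dcols))) {
    ic <- ix$idx[, j]
    dxp[ic] <- dxp[ic] + dcols[, j]
  }
  dx <- if (pad > 0)
    dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

# 1x1 convolution specialised as a channel-mixing matmul
conv1x1Init <- function(inC, outC, gain = 1) {
  list(W = matrix(rnorm(inC * outC, 0, gain / sqrt(inC)), inC, outC),
       b = numeric(outC))
}

conv1x1Forward <- function(x, par) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  out <- sweep(xm %*% par$W, 2, par$b, "+")
  dim(out) <- c(d[1], d[2], d[4], ncol(par$W))
  list(out = aperm(out, c(1, 2, 4, 3)), cache = list(xm = xm, dimIn = d))
}

conv1x1Backward <- function(dout, par, cache) {
  d <- cache$dimIn
  dmat <- aperm(dout, c(1, 2, 4, 3))
  dim(dmat) <- c(d[1] * d[2] * d[4], ncol(par$W))
  dW <- crossprod(cache$xm, dmat)
  db <- colSums(dmat)
  dxm <- dmat %*% t(par$W)
  dim(dxm) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dxm, c(1, 2, 4, 3)), grads = list(W = dW, b = db))
}

lreluForward <- function(x, alpha = 0.2) {
  neg <- x < 0
  out <- x
  out[neg] <- alpha * x[neg]
  list(out = out, cache = list(neg = neg, alpha = alpha))
}

lreluBackward <- function(dout, cache) {
  dout[cache$neg] <- cache$alpha * dout[cache$neg]
  dout
}

tanhForward <- function(x) {
  th <- tanh(x)
  list(out = th, cache = th)
}

tanhBackward <- function(dout, th) dout * (1 - th^2)

upsample2Forward <- function(x) {
  d <- dim(x)
  list(out = x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
               drop = FALSE],
       cache = d)
}

upsample2Backward <- function(dout, d) {
  od <- dim(dout)
  ev <- seq(2, od[1], by = 2); odd <- seq(1, od[1], by = 2)
  evc <- seq(2, od[2], by = 2); oddc <- seq(1, od[2], by = 2)
  dout[odd, oddc, , , drop = FALSE] + dout[ev, oddc, , , drop = FALSE] +
    dout[odd, evc, , , drop = FALSE] + dout[ev, evc, , , drop = FALSE]
}

# ---- 3D convolution (spatio-temporal, for the patch discriminator) ---------

im2colIndex3d <- function(H, W, C, T, kh, kw, kt, sh, sw, st, ph, pw, pt) {
  key <- paste("c3", H, W, C, T, kh, kw, kt, sh, sw, st, ph, pw, pt, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2 * ph; Wp <- W + 2 * pw; Tp <- T + 2 * pt
  Ho <- (Hp - kh) %/% sh + 1L
  Wo <- (Wp - kw) %/% sw + 1L
  To <- (Tp - kt) %/% st + 1L
  frameLen <- Hp * Wp * C
  iVec <- rep(sh * (0:(Ho - 1)), times = Wo * To)
  jVec <- rep(rep(sw * (0:(Wo - 1)), each = Ho), times = To)
  tVec <- rep(st * (0:(To - 1)), each = Ho * Wo)
  base <- iVec + jVec * Hp + tVec * frameLen
  nK <- kh * kw * kt * C
  di <- rep(1:kh, times = nK / kh)
  dj <- rep(rep(1:kw, each = kh), times = kt * C)
  dt <- rep(rep(1:kt, each = kh * kw), times = C)
  ch <- rep(1:C, each = kh * kw * kt)
  off <- di + (dj - 1) * Hp + (ch - 1) * Hp * Wp + (dt - 1) * frameLen
  idx <- outer(base, off, "+")
  res <- list(idx = idx, Ho = Ho, Wo = Wo, To = To, Hp = Hp, Wp = Wp, Tp = Tp)
  .idxCache[[key]] <- res
  res
}

conv3dInit <- function(inC, outC, kh, kw, kt, gain = sqrt(2)) {
  fan <- kh * kw * kt * inC
  list(W = matrix(rnorm(fan * outC, 0, gain / sqrt(fan)), fan, outC),
       b = numeric(outC))
}

conv3dForward <- function(x, par, kh, kw, kt, sh = 2L, sw = 2L, st = 1L,
                          ph = (kh - 1L) %/% 2L, pw = (kw - 1L) %/% 2L,
                          pt = (kt - 1L) %/% 2L) {
  d <- dim(x) # (H, W, C, T)
  ix <- im2colIndex3d(d[1], d[2], d[3], d[4], kh, kw, kt, sh, sw, st,
                      ph, pw, pt)
  xp <- array(0, c(ix$Hp, ix$Wp, d[3], ix$Tp))
  xp[ph + seq_len(d[1]), pw + seq_len(d[2]), , pt + seq_len(d[4])] <- x
  cols <- xp[ix$idx]
  dim(cols) <- dim(ix$idx)
  out <- sweep(cols %*% par$W, 2, par$b, "+")
  dim(out) <- c(ix$Ho, ix$Wo, ix$To, ncol(par$W))
  out <- aperm(out, c(1, 2, 4, 3)) # (Ho, Wo, outC, To)
  list(out = out, cache = list(cols = cols, ix = ix, dimIn = d,
                               ph = ph, pw = pw, pt = pt))
}

conv3dBackward <- function(dout, par, cache) {
  dmat <- aperm(dout, c(1, 2, 4, 3))
  dim(dmat) <- c(nrow(cache$cols), ncol(par$W))
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(par$W)
  d <- cache$dimIn; ix <- cache$ix
  dxp <- array(0, c(ix$Hp, ix$Wp, d[3], ix$Tp))
  for (j in seq_len(ncol(dcols))) {
    ic <- ix$idx[, j]
    dxp[ic] <- dxp[ic] + dcols[, j]
  }
  dx <- dxp[cache$ph + seq_len(d[1]), cache$pw + seq_len(d[2]), ,
            cache$pt + seq_len(d[4]), drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- Adam optimiser ---------------------------------------------------------

adamInit <- function(params) {
  zero <- function(p) {p[] <- 0; p}
  list(m = lapply(params, function(l) lapply(l, zero)),
       v = lapply(params, function(l) lapply(l, zero)),
       t = 0L)
}

adamStep <- function(params, grads, opt, lr = 1e-4, beta1 = 0, beta2 = 0.99,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (l in names(params)) for (w in names(params[[l]])) {
    g <- grads[[l]][[w]]
    opt$m[[l]][[w]] <- beta1 * opt$m[[l]][[w]] + (1 - beta1) * g
    opt$v[[l]][[w]] <- beta2 * opt$v[[l]][[w]] + (1 - beta2) * g^2
    mh <- opt$m[[l]][[w]] / c1
    vh <- opt$v[[l]][[w]] / c2
    params[[l]][[w]] <- params[[l]][[w]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, opt = opt)
}

# accumulate a layer's gradient into a gradient list
gradAcc <- function(grads, name, g) {
  if (is.null(grads[[name]])) grads[[name]] <- g
  else for (w in names(g)) grads[[name]][[w]] <- grads[[name]][[w]] + g[[w]]
  grads
}
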