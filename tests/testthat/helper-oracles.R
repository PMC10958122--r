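# Independent brute-force oracles used to validate the implementation.
# These are deliberately written with plain loops and none of the package's
# vectorised machinery.

# rasterise a disc by looping over every pixel
oracleDisc <- function(H, W, cy, cx, r) {
  m <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- 1
  m
}

# brute-force binary dilation: max over the translated structuring element
oracleDilate <- function(mask, kern) {
  H <- nrow(mask); W <- ncol(mask)
  kr <- (nrow(kern) - 1) / 2; kc <- (ncol(kern) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- 0
    for (a in seq_len(nrow(kern))) for (b in seq_len(ncol(kern))) {
      if (kern[a, b] == 0) next
      ii <- i - (a - kr - 1); jj <- j - (b - kc - 1)
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && mask[ii, jj] == 1) v <- 1
    }
    out[i, j] <- v
  }
  out
}

# per-pixel application of the two-criterion specular detection rule
# (no connected-component filtering)
oracleDetect <- function(frame, params) {
  H <- dim(frame)[1]; W <- dim(frame)[2]
  r <- (params$localWindow - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    px <- frame[i, j, ]
    v <- max(px); mn <- min(px)
    s <- if (v == 0) 0 else (v - mn) / v
    hit <- v > params$absoluteIntensity && s < params$absoluteSaturation
    if (!hit) for (ch in 1:3) {
      vals <- c()
      for (a in (i - r):(i + r)) for (b in (j - r):(j + r)) {
        aa <- min(max(a, 1), H); bb <- min(max(b, 1), W)
        vals <- c(vals, frame[aa, bb, ch])
      }
      med <- median(vals)
      if (frame[i, j, ch] > params$relativeRatio * med) {hit <- TRUE; break}
    }
    out[i, j] <- hit * 1
  }
  out
}

# brute-force masked MSE with explicit loops
oracleMaskedMSE <- function(ref, test, roi, peak = 255) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(roi))) for (j in seq_len(ncol(roi))) {
    if (roi[i, j] != 1) next
    for (ch in seq_len(dim(ref)[3]))
      tot <- tot + ((ref[i, j, ch] - test[i, j, ch]) * peak)^2
    n <- n + 1
  }
  tot / (n * dim(ref)[3])
}

# rotation angle via an independent quaternion conversion
oracleRotationAngleDeg <- function(R) {
  qw <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
  2 * acos(min(1, abs(qw))) * 180 / pi
}

# unbatched straight-line reference of the transformer stack: plain loops,
# no im2col, no batching
oracleConv2d <- function(x, W, b, k, stride) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; T <- d[4]
  pad <- (k - 1) %/% 2
  outC <- length(b)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (Wd + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, outC, T))
  for (t in seq_len(T)) for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
    patch <- numeric(k * k * C)
    n <- 0
    for (ch in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
      ii <- stride * (oi - 1) + di - pad
      jj <- stride * (oj - 1) + dj - pad
      n <- n + 1
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd)
        patch[n] <- x[ii, jj, ch, t]
    }
    for (oc in seq_len(outC))
      out[oi, oj, oc, t] <- sum(patch * W[, oc]) + b[oc]
  }
  out
}

oracleLrelu <- function(x, a = 0.2) ifelse(x > 0, x, a * x)

# reference implementation of one attention layer with explicit loops
oracleAttnLayer <- function(f, p, l, config, maskFeat) {
  d <- dim(f); h <- d[1]; w <- d[2]; C <- d[3]; T <- d[4]
  nh <- length(config$heads); cg <- C / nh
  lin <- function(x, par) { # 1x1 conv by looping over positions
    out <- array(0, c(h, w, ncol(par$W), T))
    for (t in seq_len(T)) for (i in seq_len(h)) for (j in seq_len(w))
      out[i, j, , t] <- as.numeric(crossprod(par$W, x[i, j, , t])) + par$b
    out
  }
  q <- lin(f, p[[sprintf("l%d.Wq", l)]])
  k <- lin(f, p[[sprintf("l%d.Wk", l)]])
  v <- lin(f, p[[sprintf("l%d.Wv", l)]])
  att <- array(0, c(h, w, C, T))
  for (g in seq_len(nh)) {
    r1 <- config$heads[[g]][1]; r2 <- config$heads[[g]][2]
    chIdx <- ((g - 1) * cg + 1):(g * cg)
    npr <- h / r1; npc <- w / r2
    # enumerate patches (frame, pi, pj) with contents and validity
    plist <- list()
    for (t in seq_len(T)) for (pj in seq_len(npc)) for (pi in seq_len(npr)) {
      rows <- ((pi - 1) * r1 + 1):(pi * r1)
      cols <- ((pj - 1) * r2 + 1):(pj * r2)
      plist[[length(plist) + 1]] <- list(
        t = t, rows = rows, cols = cols,
        q = q[rows, cols, chIdx, t], k = k[rows, cols, chIdx, t],
        v = v[rows, cols, chIdx, t],
        valid = all(maskFeat[rows, cols, t] == 0))
    }
    N <- length(plist)
    dd <- r1 * r2 * cg
    for (i in seq_len(N)) {
      s <- numeric(N)
      for (j in seq_len(N))
        s[j] <- sum(as.numeric(plist[[i]]$q) * as.numeric(plist[[j]]$k)) / dd
      valid <- vapply(plist, `[[`, logical(1), "valid")
      o <- array(0, c(r1, r2, cg))
      if (any(valid)) {
        e <- exp(s[valid] - max(s[valid]))
        al <- numeric(N); al[valid] <- e / sum(e)
        for (j in seq_len(N)) if (al[j] > 0)
          o <- o + al[j] * array(plist[[j]]$v, c(r1, r2, cg))
      }
      pp <- plist[[i]]
      att[pp$rows, pp$cols, chIdx, pp$t] <- o
    }
  }
  of <- lin(att, p[[sprintf("l%d.Wo", l)]])
  f2 <- f + of
  g1 <- oracleConv2d(f2, p[[sprintf("l%d.ffn1", l)]]$W,
                     p[[sprintf("l%d.ffn1", l)]]$b, 3, 1)
  g2 <- oracleConv2d(oracleLrelu(g1), p[[sprintf("l%d.ffn2", l)]]$W,
                     p[[sprintf("l%d.ffn2", l)]]$b, 3, 1)
  f2 + g2
}

# feature-scale mask by explicit block maximum
oracleBlockMax <- function(M, f) {
  H <- dim(M)[1]; W <- dim(M)[2]; T <- dim(M)[3]
  out <- array(0, c(H / f, W / f, T))
  for (t in seq_len(T)) for (i in seq_len(H / f)) for (j in seq_len(W / f))
    out[i, j, t] <- max(M[((i - 1) * f + 1):(i * f),
                          ((j - 1) * f + 1):(j * f), t])
  out
}

# small deterministic random RGB frame
randFrame <- function(H, W, seed = 1) {
  set.seed(seed)
  array(runif(H * W * 3), c(H, W, 3))
}
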