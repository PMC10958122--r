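# internal helpers shared across modules

# run expr with a local RNG seed, restoring global state afterwards
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# luminance of an (H, W, 3) array
rgb2gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# HSV-style saturation and value of an (H, W, 3) array
rgbValue <- function(img) pmax(img[, , 1], pmax(img[, , 2], img[, , 3]))
rgbSaturation <- function(img) {
  mx <- rgbValue(img)
  mn <- pmin(img[, , 1], pmin(img[, , 2], img[, , 3]))
  s <- (mx - mn) / pmax(mx, 1e-12)
  s[mx == 0] <- 0
  s
}

# bilinear sampling of a matrix at (possibly fractional) row/col coordinates;
# out-of-range samples are clamped to the border
bilinearSample <- function(m, rows, cols) {
  H <- nrow(m); W <- ncol(m)
  rows <- pmin(pmax(rows, 1), H)
  cols <- pmin(pmax(cols, 1), W)
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- rows - r0; fc <- cols - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc +
    m[cbind(r1, c1)] * fr * fc
}

# separable convolution of a matrix with a 1-D kernel (replicate padding)
sepConv <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  H <- nrow(m); W <- ncol(m)
  ridx <- pmin(pmax(seq_len(H + 2 * r) - r, 1), H)
  cidx <- pmin(pmax(seq_len(W + 2 * r) - r, 1), W)
  mp <- m[ridx, , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + H - 1), , drop = FALSE]
  mp <- out[, cidx, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * mp[, i:(i + W - 1), drop = FALSE]
  out
}

gaussKernel1d <- function(size, sigma) {
  r <- (size - 1) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# skew-symmetric cross-product matrix
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# rotation about a (unit) axis by angle in degrees
axisAngleRotation <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- skew3(axis)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-15) stop("zero-norm vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
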