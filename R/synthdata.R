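#' Specification of a synthetic endoscopy-like clip
#'
#' Describes a seeded synthetic clip: a smoothly deforming reddish
#' mucosa-like texture with vein-like curves, overlaid with saturated
#' specular blobs surrounded by darkened rings that can jump, appear and
#' disappear between frames.  The same spec and seed always produce
#' bit-identical output.
#'
#' @param frameCount number of frames T (>= 1).
#' @param frameSize integer (H, W), both >= 32.
#' @param texture list: \code{octaves} (value-noise octaves), \code{veins}
#'   (number of vein curves), \code{veinWidth} (px).
#' @param motion list: \code{driftPx} per-frame translation drift (px),
#'   \code{rotDeg} per-frame rotation (degrees), \code{wobble} amplitude of a
#'   sinusoidal wobble (px).
#' @param highlights list: \code{count}, \code{radiusRange} (px),
#'   \code{saturation} peak level, \code{ringWidth} (px), \code{ringDarken}
#'   multiplicative factor, \code{jumpProb} per-frame relocation probability,
#'   \code{visibleProb} per-frame visibility probability.
#' @param seed integer RNG seed.
#' @return an object of class \code{SyntheticSceneSpec} (a validated list).
#' @export
syntheticSceneSpec <- function(frameCount = 24,
                               frameSize = c(96, 96),
                               texture = list(octaves = 4, veins = 6, veinWidth = 2),
                               motion = list(driftPx = 1.2, rotDeg = 0.15, wobble = 0.8),
                               highlights = list(count = 6, radiusRange = c(3, 8),
                                                 saturation = 1.0, ringWidth = 2,
                                                 ringDarken = 0.55, jumpProb = 0.25,
                                                 visibleProb = 0.9),
                               seed = 1L) {
  if (frameCount < 1) stop("frameCount must be >= 1")
  if (length(frameSize) != 2 || any(frameSize < 32)) stop("frameSize must be >= 32")
  if (highlights$jumpProb < 0 || highlights$jumpProb > 1)
    stop("jumpProb must lie in [0, 1]")
  if (highlights$count < 0) stop("highlight count must be >= 0")
  structure(list(frameCount = as.integer(frameCount),
                 frameSize = as.integer(frameSize),
                 texture = texture, motion = motion,
                 highlights = highlights, seed = as.integer(seed)),
            class = "SyntheticSceneSpec")
}

# multi-octave value noise on an (H, W) grid, values roughly in [0, 1]
valueNoise <- function(H, W, octaves) {
  out <- matrix(0, H, W)
  amp <- 1; tot <- 0
  for (o in seq_len(octaves)) {
    n <- 2^(o + 1)
    g <- matrix(runif((n + 1)^2), n + 1, n + 1)
    rows <- seq(1, n + 1 - 1e-9, length.out = H)
    cols <- seq(1, n + 1 - 1e-9, length.out = W)
    out <- out + amp * bilinearSample(g, rep(rows, times = W),
                                      rep(cols, each = H))
    tot <- tot + amp
    amp <- amp / 2
  }
  matrix(out / tot, H, W)
}

# evaluate a cubic Bezier at parameter values u in [0, 1];
# cp is a 4 x 2 control-point matrix
bezierCubic <- function(cp, u) {
  b <- cbind((1 - u)^3, 3 * u * (1 - u)^2, 3 * u^2 * (1 - u), u^3)
  b %*% cp
}

# stamp dark vein-like Bezier curves onto an (H, W, 3) texture
paintVeins <- function(tex, nVeins, width) {
  H <- dim(tex)[1]; W <- dim(tex)[2]
  for (v in seq_len(nVeins)) {
    cp <- cbind(runif(4, 1, H), runif(4, 1, W))
    pts <- bezierCubic(cp, seq(0, 1, length.out = 4 * max(H, W)))
    shade <- runif(1, 0.35, 0.6)
    r <- max(1, round(width / 2))
    for (dr in -r:r) for (dc in -r:r) {
      if (dr * dr + dc * dc > r * r) next
      rr <- round(pts[, 1]) + dr; cc <- round(pts[, 2]) + dc
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      idx <- cbind(rr[ok], cc[ok])
      for (ch in 1:3) {
        pl <- tex[, , ch]
        pl[idx] <- pl[idx] * (if (ch == 1) shade + 0.25 else shade)
        tex[, , ch] <- pl
      }
    }
  }
  tex
}

# render the mucosa-like background canvas (larger than the frame so motion
# can sample inside it)
renderCanvas <- function(spec, margin) {
  H <- spec$frameSize[1] + 2 * margin
  W <- spec$frameSize[2] + 2 * margin
  n1 <- valueNoise(H, W, spec$texture$octaves)
  n2 <- valueNoise(H, W, spec$texture$octaves)
  tex <- array(0, c(H, W, 3))
  tex[, , 1] <- 0.55 + 0.3 * n1
  tex[, , 2] <- 0.18 + 0.18 * n2
  tex[, , 3] <- 0.12 + 0.12 * n2
  tex <- paintVeins(tex, spec$texture$veins, spec$texture$veinWidth)
  clamp01(tex)
}

# sample one frame from the canvas under a similarity transform
sampleFrame <- function(canvas, H, W, margin, dx, dy, rotDeg) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- rotDeg * pi / 180
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  rr <- g$r - cy; cc <- g$c - cx
  srcR <- cy + margin + dy + cos(th) * rr - sin(th) * cc
  srcC <- cx + margin + dx + sin(th) * rr + cos(th) * cc
  out <- array(0, c(H, W, 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinearSample(canvas[, , ch], srcR, srcC), H, W)
  out
}

#' Generate a synthetic endoscopy-like clip with ground-truth hole masks
#'
#' Renders a temporally coherent clean clip (drifting, slowly rotating
#' mucosa-like texture with veins), a per-frame binary mask marking every
#' pixel touched by a specular highlight (saturated core plus darkened
#' ring), and the corrupted clip with the highlights composited in.  The
#' corrupted clip equals the clean clip wherever the mask is 0.
#'
#' @param spec a \code{\link{syntheticSceneSpec}}.
#' @return list with elements \code{clean} (\linkS4class{VideoClip}),
#'   \code{masks} (\linkS4class{MaskSequence}) and \code{corrupted}
#'   (\linkS4class{VideoClip}).
#' @export
generateClip <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSceneSpec"))
  H <- spec$frameSize[1]; W <- spec$frameSize[2]; T <- spec$frameCount
  hp <- spec$highlights
  withSeed(spec$seed, {
    margin <- ceiling(abs(spec$motion$driftPx) * T + spec$motion$wobble + 4)
    canvas <- renderCanvas(spec, margin)
    clean <- array(0, c(H, W, 3, T))
    masksA <- array(0, c(H, W, T))
    corrupted <- array(0, c(H, W, 3, T))
    # highlight state: centres, radii, visibility
    k <- hp$count
    ctr <- if (!is.null(hp$centers)) matrix(hp$centers, k, 2)
    else cbind(runif(k, 1, H), runif(k, 1, W))
    rad <- if (k > 0) runif(k, hp$radiusRange[1], hp$radiusRange[2]) else numeric(0)
    rowIdx <- matrix(seq_len(H), H, W)
    colIdx <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (t in seq_len(T)) {
      dx <- spec$motion$driftPx * (t - 1) +
        spec$motion$wobble * sin(2 * pi * (t - 1) / max(T, 2))
      dy <- spec$motion$driftPx * 0.6 * (t - 1)
      rot <- spec$motion$rotDeg * (t - 1)
      fr <- sampleFrame(canvas, H, W, margin, dx, dy, rot)
      clean[, , , t] <- fr
      cor <- fr
      m <- matrix(0, H, W)
      if (k > 0) {
        # discontinuous highlight motion: jumps, jitter, blinking
        if (t > 1) {
          jump <- runif(k) < hp$jumpProb
          nj <- sum(jump)
          if (nj > 0) ctr[jump, ] <- cbind(runif(nj, 1, H), runif(nj, 1, W))
          jsd <- hp$jitterSd %||% 0.7
          ctr[!jump, ] <- ctr[!jump, , drop = FALSE] +
            matrix(rnorm(2 * sum(!jump), 0, jsd), ncol = 2)
        }
        visible <- runif(k) < hp$visibleProb
        for (b in seq_len(k)) {
          if (!visible[b]) next
          d2 <- (rowIdx - ctr[b, 1])^2 + (colIdx - ctr[b, 2])^2
          r <- rad[b]
          core <- d2 <= r^2
          ring <- d2 > r^2 & d2 <= (r + hp$ringWidth)^2
          w <- exp(-2 * d2 / r^2)
          for (ch in 1:3) {
            pl <- cor[, , ch]
            pl[core] <- (1 - w[core]) * pl[core] + w[core] * hp$saturation
            pl[ring] <- pl[ring] * hp$ringDarken
            cor[, , ch] <- pl
          }
          m[core | ring] <- 1
        }
      }
      corrupted[, , , t] <- clamp01(cor)
      masksA[, , t] <- m
    }
    list(clean = VideoClip(clean), masks = MaskSequence(masksA),
         corrupted = VideoClip(corrupted))
  })
}

#' Generate a calibrated two-view scene with exact ground truth
#'
#' Scatters 3D points in front of a pinhole camera, applies a known relative
#' rotation and translation, and projects into both views.  With zero pixel
#' noise the correspondences satisfy the epipolar constraint of the exact
#' essential matrix to machine precision.
#'
#' @param nPoints number of scene points (>= 8).
#' @param rotationDeg relative rotation magnitude in degrees (random axis).
#' @param translation length-3 relative translation (must be nonzero).
#' @param noisePx standard deviation of additive pixel noise.
#' @param seed RNG seed.
#' @param imageSize (H, W) of the virtual image, default \code{c(480, 640)}.
#' @param focal focal length in pixels, default 500.
#' @return a \linkS4class{TwoViewScene}.
#' @export
generateTwoViewScene <- function(nPoints, rotationDeg, translation,
                                 noisePx = 0, seed = 1L,
                                 imageSize = c(480, 640), focal = 500) {
  if (nPoints < 8) stop("nPoints must be >= 8")
  if (sqrt(sum(translation^2)) <= 0)
    stop("translation must be nonzero (essential-matrix direction undefined)")
  K <- matrix(c(focal, 0, 0, 0, focal, 0,
                imageSize[2] / 2, imageSize[1] / 2, 1), 3, 3)
  withSeed(seed, {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    R <- axisAngleRotation(axis, rotationDeg)
    pts <- NULL
    while (is.null(pts) || nrow(pts) < nPoints) {
      cand <- cbind(runif(4 * nPoints, -1.2, 1.2),
                    runif(4 * nPoints, -0.9, 0.9),
                    runif(4 * nPoints, 2.5, 6))
      X2 <- t(R %*% t(cand) + translation)
      ok <- cand[, 3] > 0 & X2[, 3] > 0
      p1 <- t(K %*% t(cand / cand[, 3]))[, 1:2, drop = FALSE]
      p2 <- t(K %*% t(X2 / X2[, 3]))[, 1:2, drop = FALSE]
      inb <- function(p) p[, 1] >= 1 & p[, 1] <= imageSize[2] &
        p[, 2] >= 1 & p[, 2] <= imageSize[1]
      ok <- ok & inb(p1) & inb(p2)
      pts <- rbind(pts, cand[ok, , drop = FALSE])
    }
    pts <- pts[seq_len(nPoints), , drop = FALSE]
    X2 <- t(R %*% t(pts) + translation)
    p1 <- t(K %*% t(pts / pts[, 3]))[, 1:2, drop = FALSE]
    p2 <- t(K %*% t(X2 / X2[, 3]))[, 1:2, drop = FALSE]
    if (noisePx > 0) {
      p1 <- p1 + matrix(rnorm(length(p1), 0, noisePx), ncol = 2)
      p2 <- p2 + matrix(rnorm(length(p2), 0, noisePx), ncol = 2)
    }
    new("TwoViewScene", points3d = pts, intrinsics = K,
        rotationGT = R, translationGT = as.numeric(translation),
        proj1 = p1, proj2 = p2)
  })
}

#' Generate a rectified stereo pair with known disparity
#'
#' Renders a textured left image from a scene spec and warps it horizontally
#' by a nonnegative disparity field to obtain the right image:
#' \code{right(r, c) = left(r, c + d(r, c))}.
#'
#' @param spec a \code{\link{syntheticSceneSpec}} (texture/seed are used).
#' @param disparity either a nonnegative \code{(H, W)} matrix or a function
#'   \code{f(rows, cols)} returning disparity values for matrices of pixel
#'   coordinates.
#' @return list with \code{left}, \code{right} (arrays \code{(H, W, 3)}) and
#'   \code{disparityGT} (matrix \code{(H, W)}).
#' @export
generateStereoPair <- function(spec, disparity) {
  stopifnot(inherits(spec, "SyntheticSceneSpec"))
  H <- spec$frameSize[1]; W <- spec$frameSize[2]
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- if (is.function(disparity)) disparity(rows, cols) else disparity
  d <- matrix(d, H, W)
  if (any(d < 0)) stop("disparity must be nonnegative")
  left <- withSeed(spec$seed, {
    canvas <- renderCanvas(spec, 0)
    canvas[seq_len(H), seq_len(W), , drop = FALSE]
  })
  right <- array(0, c(H, W, 3))
  for (ch in 1:3)
    right[, , ch] <- matrix(bilinearSample(left[, , ch], as.vector(rows),
                                           as.vector(cols + d)), H, W)
  list(left = left, right = right, disparityGT = d)
}

#' Exact essential matrix of a two-view scene
#'
#' @param scene a \linkS4class{TwoViewScene}.
#' @return the 3 x 3 essential matrix \code{[t]_x R}.
#' @export
essentialMatrixGT <- function(scene) {
  skew3(unitize(scene@translationGT)) %*% scene@rotationGT
}
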