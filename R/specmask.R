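#' Detection parameters for chromaticity-based specular segmentation
#'
#' The detector follows the dichromatic-reflection-model family of rules:
#' a pixel is specular if it is (i) absolutely bright and desaturated, or
#' (ii) much brighter than its local surroundings in any colour channel.
#'
#' @param absoluteIntensity intensity (HSV value) threshold in \code{[0,1]}.
#' @param absoluteSaturation saturation threshold in \code{[0,1]}; the
#'   absolute rule fires when saturation is below this.
#' @param relativeRatio per-channel ratio over the local median (> 1).
#' @param localWindow odd window size (px) for the local median.
#' @param minRegionArea connected components smaller than this (px^2) are
#'   discarded.
#' @return a validated parameter list of class \code{DetectionParams}.
#' @export
detectionParams <- function(absoluteIntensity = 0.85,
                            absoluteSaturation = 0.25,
                            relativeRatio = 1.5,
                            localWindow = 15L,
                            minRegionArea = 5L) {
  if (absoluteIntensity < 0 || absoluteIntensity > 1)
    stop("absoluteIntensity must lie in [0, 1]")
  if (absoluteSaturation < 0 || absoluteSaturation > 1)
    stop("absoluteSaturation must lie in [0, 1]")
  if (relativeRatio <= 1) stop("relativeRatio must exceed 1")
  if (localWindow < 3 || localWindow %% 2 == 0)
    stop("localWindow must be an odd integer >= 3")
  structure(list(absoluteIntensity = absoluteIntensity,
                 absoluteSaturation = absoluteSaturation,
                 relativeRatio = relativeRatio,
                 localWindow = as.integer(localWindow),
                 minRegionArea = as.integer(minRegionArea)),
            class = "DetectionParams")
}

# local median filter with replicate padding, window w (odd)
localMedian <- function(m, w) {
  r <- (w - 1L) / 2L
  H <- nrow(m); W <- ncol(m)
  ridx <- pmin(pmax(seq_len(H + 2 * r) - r, 1), H)
  cidx <- pmin(pmax(seq_len(W + 2 * r) - r, 1), W)
  mp <- m[ridx, cidx]
  # EBImage medianFilter operates on [0,1] images with square windows
  out <- EBImage::medianFilter(mp, r)
  out[(r + 1):(r + H), (r + 1):(r + W)]
}

#' Detect specular highlights in a single RGB frame
#'
#' Applies the two-criterion chromaticity rule described in
#' \code{\link{detectionParams}} and removes small connected components.
#'
#' @param frame numeric \code{(H, W, 3)} array with values in \code{[0, 1]}.
#' @param params a \code{\link{detectionParams}} object.
#' @return binary \code{(H, W)} matrix (1 = specular).
#' @export
detectSpecularMask <- function(frame, params = detectionParams()) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("frame must be an (H, W, 3) RGB array")
  v <- rgbValue(frame)
  s <- rgbSaturation(frame)
  absRule <- v > params$absoluteIntensity & s < params$absoluteSaturation
  relRule <- matrix(FALSE, nrow(v), ncol(v))
  for (ch in 1:3) {
    med <- localMedian(frame[, , ch], params$localWindow)
    relRule <- relRule | frame[, , ch] > params$relativeRatio * med
  }
  m <- absRule | relRule
  if (params$minRegionArea > 1 && any(m)) {
    lab <- EBImage::bwlabel(m * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$minRegionArea)
    m <- matrix(lab %in% keep, nrow(v), ncol(v))
  }
  m * 1
}

#' Detect specular highlights over a whole clip
#'
#' @param clip a \linkS4class{VideoClip}.
#' @param params a \code{\link{detectionParams}} object.
#' @return a \linkS4class{MaskSequence}.
#' @export
detectSpecularClip <- function(clip, params = detectionParams()) {
  T <- nFrames(clip)
  out <- array(0, c(frameSize(clip), T))
  for (t in seq_len(T)) out[, , t] <- detectSpecularMask(clip[[t]], params)
  MaskSequence(out)
}

#' Morphological structuring elements
#'
#' Builds the binary structuring elements used throughout mask processing:
#' \code{"diamond"} (L1 ball of the given radius), \code{"ball"} (Euclidean
#' disc) and \code{"ellipse"} (axis-aligned ellipse with radii
#' \code{(a, b)} = (rows, cols)).
#'
#' @param element one of \code{"diamond"}, \code{"ball"}, \code{"ellipse"}.
#' @param radius a single radius, or \code{c(a, b)} for \code{"ellipse"}.
#' @return a 0/1 matrix of odd dimensions.
#' @export
structuringElement <- function(element = c("diamond", "ball", "ellipse"),
                               radius) {
  element <- match.arg(element)
  if (any(radius < 0)) stop("radius must be >= 0")
  if (element == "ellipse") {
    if (length(radius) == 1) radius <- c(radius, radius)
    a <- radius[1]; b <- radius[2]
    rr <- -ceiling(a):ceiling(a); cc <- -ceiling(b):ceiling(b)
    k <- outer(rr, cc, function(r, c)
      (r / max(a, 1e-9))^2 + (c / max(b, 1e-9))^2 <= 1 + 1e-12)
    if (a == 0 && b == 0) k <- matrix(TRUE, 1, 1)
  } else {
    r <- radius[1]
    rr <- -ceiling(r):ceiling(r)
    k <- if (element == "diamond")
      outer(rr, rr, function(i, j) abs(i) + abs(j) <= r + 1e-12)
    else
      outer(rr, rr, function(i, j) i^2 + j^2 <= r^2 + 1e-12)
    if (r == 0) k <- matrix(TRUE, 1, 1)
  }
  k * 1
}

#' Dilate a binary mask with a named structuring element
#'
#' @param mask binary \code{(H, W)} matrix.
#' @param element \code{"diamond"}, \code{"ball"} or \code{"ellipse"}.
#' @param radius radius (or \code{c(a, b)} radii for \code{"ellipse"}).
#' @return dilated binary matrix (always a superset of the input).
#' @export
dilateMask <- function(mask, element = c("diamond", "ball", "ellipse"),
                       radius) {
  element <- match.arg(element)
  if (any(radius < 0)) stop("radius must be >= 0")
  if (all(radius == 0) || !any(mask != 0)) return((mask != 0) * 1)
  k <- structuringElement(element, radius)
  (EBImage::dilate((mask != 0) * 1, k) != 0) * 1
}

# translate a binary mask by (dx, dy) = (columns right, rows down);
# content shifted beyond the frame is cropped
translateMask <- function(mask, dx, dy) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  src <- which(mask != 0, arr.ind = TRUE)
  if (nrow(src) == 0) return(out)
  rr <- src[, 1] + round(dy); cc <- src[, 2] + round(dx)
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  out[cbind(rr[ok], cc[ok])] <- 1
  out
}

#' Pseudo-ground-truth mask specification
#'
#' The pseudo-GT construction translates detected specularity masks onto
#' unoccluded texture so that the content behind the (translated) mask is
#' known, enabling paired training and evaluation without real ground
#' truth.  The translation is fixed for an entire sequence.
#'
#' @param translation \code{c(dx, dy)} pixel shift (columns, rows); must be
#'   nonzero.  Defaults to "to the right" by 20\% of the frame width when
#'   built via \code{\link{makePseudoMasks}} with \code{translation = NULL}.
#' @param guardRadius ball-dilation radius applied to the original mask
#'   before overlap removal.
#' @param ellipseRadii \code{c(a, b)} elliptical dilation radii covering the
#'   dark rings around specularities.
#' @param diamondRadius diamond dilation applied to the raw detection.
#' @param variant \code{"training"} (dilate, then translate, then remove
#'   overlap) or \code{"evaluation"} (translate, remove overlap, then
#'   dilate).
#' @return a validated list of class \code{PseudoGTSpec}.
#' @export
pseudoGTSpec <- function(translation, guardRadius = 3, ellipseRadii = c(5, 3),
                         diamondRadius = 1,
                         variant = c("training", "evaluation")) {
  variant <- match.arg(variant)
  if (all(translation == 0)) stop("translation must be nonzero")
  if (any(c(guardRadius, ellipseRadii, diamondRadius) < 0))
    stop("radii must be >= 0")
  structure(list(translation = translation, guardRadius = guardRadius,
                 ellipseRadii = ellipseRadii, diamondRadius = diamondRadius,
                 variant = variant),
            class = "PseudoGTSpec")
}

#' Build a pseudo-ground-truth mask from a raw specularity detection
#'
#' Training variant: the detection is dilated with the elliptical element
#' (to cover dark rings), translated by the fixed per-sequence offset, and
#' every pixel overlapping the guard-dilated original detection is removed.
#' Evaluation variant: the detection is translated first, overlap with the
#' guard-dilated original removed, then dilated with the elliptical
#' element.  In both variants the result is guaranteed disjoint from the
#' guard-dilated original (for the evaluation variant the overlap removal
#' is re-applied after the final dilation, since dilation can otherwise
#' re-enter the guard zone).
#'
#' @param segMask raw detection mask (\code{(H, W)} binary matrix, the
#'   diamond-dilated segmentation stage).
#' @param spec a \code{\link{pseudoGTSpec}}.
#' @return binary \code{(H, W)} pseudo-GT mask.
#' @export
makePseudoMask <- function(segMask, spec) {
  stopifnot(inherits(spec, "PseudoGTSpec"))
  dx <- spec$translation[1]; dy <- spec$translation[2]
  guard <- dilateMask(segMask, "ball", spec$guardRadius)
  if (spec$variant == "training") {
    m <- dilateMask(segMask, "ellipse", spec$ellipseRadii)
    m <- translateMask(m, dx, dy)
    m <- m * (1 - guard)
  } else {
    m <- translateMask(segMask, dx, dy)
    m <- m * (1 - guard)
    m <- dilateMask(m, "ellipse", spec$ellipseRadii)
    m <- m * (1 - guard)
  }
  m
}

#' Pseudo-ground-truth masks for a whole sequence
#'
#' Detects specular highlights in every frame (or takes precomputed
#' detections), applies the diamond dilation of the segmentation stage, and
#' builds pseudo-GT masks with one fixed translation for the entire
#' sequence.
#'
#' @param clip a \linkS4class{VideoClip}, or \code{NULL} when
#'   \code{detections} are given.
#' @param spec a \code{\link{pseudoGTSpec}}; when its translation is
#'   \code{NULL} the default \code{(+0.2 * W, 0)} is used.
#' @param params \code{\link{detectionParams}} for the segmentation stage.
#' @param detections optional precomputed raw \linkS4class{MaskSequence}.
#' @return list with \code{pseudo} (\linkS4class{MaskSequence}),
#'   \code{segmentation} (diamond-dilated detections) and
#'   \code{translation} used.
#' @export
makePseudoMasks <- function(clip = NULL, spec = NULL,
                            params = detectionParams(), detections = NULL) {
  if (is.null(detections)) detections <- detectSpecularClip(clip, params)
  sz <- frameSize(detections)
  if (is.null(spec))
    spec <- pseudoGTSpec(translation = c(round(0.2 * sz[2]), 0))
  T <- nFrames(detections)
  segA <- array(0, c(sz, T)); psA <- array(0, c(sz, T))
  for (t in seq_len(T)) {
    seg <- dilateMask(detections[[t]], "diamond", spec$diamondRadius)
    segA[, , t] <- seg
    psA[, , t] <- makePseudoMask(seg, spec)
  }
  list(pseudo = MaskSequence(psA), segmentation = MaskSequence(segA),
       translation = spec$translation)
}

#' Temporal random masks moving along a cubic Bezier trajectory
#'
#' Generates one random blob shape per sequence and moves its centroid
#' along a cubic Bezier curve sampled at T points, giving smoothly moving
#' free-form masks used during the initialisation training phase.
#'
#' @param T number of frames (>= 1).
#' @param frameSize integer (H, W).
#' @param seed RNG seed.
#' @param shapeRadius mean blob radius in px (default scales with frame).
#' @param controlPoints optional 4 x 2 matrix of Bezier control points in
#'   (row, col) coordinates; random when \code{NULL}.
#' @return a \linkS4class{MaskSequence}.
#' @export
bezierRandomMasks <- function(T, frameSize, seed = 1L, shapeRadius = NULL,
                              controlPoints = NULL) {
  if (T < 1) stop("T must be >= 1")
  H <- frameSize[1]; W <- frameSize[2]
  if (H < 1 || W < 1) stop("invalid frame size")
  withSeed(seed, {
    rad <- shapeRadius %||% max(4, round(min(H, W) / 8))
    # star-shaped random blob: radius modulated over angle by smooth noise
    nang <- 72
    ang <- seq(0, 2 * pi, length.out = nang + 1)[-(nang + 1)]
    wob <- rad * (0.75 + 0.5 * runif(5))
    rr <- rad + 0.35 * rad * (sin(ang * 2 + wob[1]) * runif(1) +
                                sin(ang * 3 + wob[2]) * 0.5 * runif(1))
    # rasterise the blob once, centred in its own stamp
    sr <- ceiling(max(rr)) + 1
    stamp <- matrix(0, 2 * sr + 1, 2 * sr + 1)
    gy <- matrix(-sr:sr, 2 * sr + 1, 2 * sr + 1)
    gx <- t(gy)
    pa <- atan2(gx, gy) %% (2 * pi)
    pr <- sqrt(gx^2 + gy^2)
    ri <- pmin(nang, 1 + floor(pa / (2 * pi) * nang))
    stamp[pr <= rr[ri]] <- 1
    # control points spaced so the trajectory stays smooth: the Bezier
    # velocity is bounded by 3 max|P_{i+1} - P_i|, so per-frame centroid
    # displacement <= 3 maxSeg / (T - 1); keep that below half the radius
    cp <- controlPoints
    if (is.null(cp)) {
      maxSeg <- max(2, 0.4 * rad * max(T - 1, 1) / 3)
      p <- c(runif(1, sr + 1, H - sr), runif(1, sr + 1, W - sr))
      cp <- matrix(0, 4, 2)
      cp[1, ] <- p
      for (i in 2:4) {
        ang <- runif(1, 0, 2 * pi)
        step <- runif(1, 0, maxSeg)
        p <- p + step * c(cos(ang), sin(ang))
        p[1] <- min(max(p[1], sr + 1), H - sr)
        p[2] <- min(max(p[2], sr + 1), W - sr)
        cp[i, ] <- p
      }
    }
    u <- if (T == 1) 0 else seq(0, 1, length.out = T)
    path <- bezierCubic(cp, u)
    out <- array(0, c(H, W, T))
    for (t in seq_len(T)) {
      m <- matrix(0, H, W)
      cy <- round(path[t, 1]); cx <- round(path[t, 2])
      src <- which(stamp == 1, arr.ind = TRUE)
      rr2 <- src[, 1] - sr - 1 + cy; cc2 <- src[, 2] - sr - 1 + cx
      ok <- rr2 >= 1 & rr2 <= H & cc2 >= 1 & cc2 <= W
      m[cbind(rr2[ok], cc2[ok])] <- 1
      out[, , t] <- m
    }
    MaskSequence(out)
  })
}
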