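#' @import methods
#' @importFrom stats median quantile rnorm runif sd setNames
#' @importFrom utils head tail write.csv read.csv
NULL

#' VideoClip: an ordered sequence of RGB frames
#'
#' Container for a video clip as a dense numeric array of shape
#' \code{(H, W, 3, T)} with values in \code{[0, 1]}.  All pipeline stages
#' (detection, pseudo-mask generation, inpainting, evaluation) exchange
#' clips in this form; PNG frame directories are converted with
#' \code{\link{readFrames}} / \code{\link{writeFrames}}.
#'
#' @slot frames numeric array \code{(H, W, 3, T)}, values in \code{[0, 1]}.
#' @export
setClass("VideoClip", representation(frames = "array"))

setValidity("VideoClip", function(object) {
  d <- dim(object@frames)
  if (length(d) != 4L) return("frames must be a (H, W, 3, T) array")
  if (d[3] != 3L) return("frames must have 3 colour channels")
  if (d[1] < 1L || d[2] < 1L || d[4] < 1L) return("empty clip")
  v <- range(object@frames)
  if (!all(is.finite(v))) return("frames contain non-finite values")
  if (v[1] < -1e-8 || v[2] > 1 + 1e-8) return("frame values must lie in [0, 1]")
  TRUE
})

#' Construct a VideoClip
#'
#' @param frames numeric array \code{(H, W, 3, T)} or \code{(H, W, 3)} for a
#'   single frame, values in \code{[0, 1]}.
#' @return a \linkS4class{VideoClip}.
#' @export
VideoClip <- function(frames) {
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  new("VideoClip", frames = frames)
}

#' MaskSequence: per-frame binary hole masks
#'
#' Binary masks paired with a \linkS4class{VideoClip}; value 1 marks a hole
#' pixel (to be inpainted), 0 a valid pixel.  Stored as a numeric array of
#' shape \code{(H, W, T)}.
#'
#' @slot masks numeric array \code{(H, W, T)} with values in \code{\{0, 1\}}.
#' @export
setClass("MaskSequence", representation(masks = "array"))

setValidity("MaskSequence", function(object) {
  d <- dim(object@masks)
  if (length(d) != 3L) return("masks must be a (H, W, T) array")
  if (!all(object@masks %in% c(0, 1))) return("mask values must be 0 or 1")
  TRUE
})

#' Construct a MaskSequence
#'
#' @param masks numeric/logical array \code{(H, W, T)} or matrix
#'   \code{(H, W)} for a single frame; nonzero values become holes.
#' @return a \linkS4class{MaskSequence}.
#' @export
MaskSequence <- function(masks) {
  masks <- (masks != 0) * 1
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  new("MaskSequence", masks = masks)
}

#' TwoViewScene: a calibrated two-view geometry with exact ground truth
#'
#' @slot points3d N x 3 matrix of scene points (camera-1 frame).
#' @slot intrinsics 3 x 3 calibration matrix.
#' @slot rotationGT 3 x 3 ground-truth relative rotation.
#' @slot translationGT length-3 ground-truth relative translation.
#' @slot proj1,proj2 N x 2 pixel projections in each view.
#' @export
setClass("TwoViewScene", representation(
  points3d = "matrix", intrinsics = "matrix",
  rotationGT = "matrix", translationGT = "numeric",
  proj1 = "matrix", proj2 = "matrix"))

setValidity("TwoViewScene", function(object) {
  R <- object@rotationGT
  if (abs(det(R) - 1) > 1e-6 || max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotationGT must be a proper rotation")
  if (nrow(object@proj1) != nrow(object@proj2))
    return("projection counts differ between views")
  TRUE
})

#' MatchSet: keypoint correspondences between two frames
#'
#' @slot keypointsA,keypointsB N x 2 keypoint pixel coordinates (x, y).
#' @slot matches M x 2 index pairs (into A and B keypoints) surviving the
#'   ratio test.
#' @slot distances descriptor distances of the kept matches.
#' @slot ratioThreshold the Lowe ratio used.
#' @slot flag character; "" or a diagnostic such as "empty".
#' @export
setClass("MatchSet", representation(
  keypointsA = "matrix", keypointsB = "matrix",
  matches = "matrix", distances = "numeric",
  ratioThreshold = "numeric", flag = "character"))

setValidity("MatchSet", function(object) {
  m <- object@matches
  if (nrow(m) > 0) {
    if (max(m[, 1]) > nrow(object@keypointsA) || max(m[, 2]) > nrow(object@keypointsB))
      return("match indices out of range")
    if (min(m) < 1) return("match indices must be 1-based positive")
  }
  TRUE
})

#' @rdname MatchSet-class
#' @param keypointsA,keypointsB keypoint coordinate matrices.
#' @param matches index-pair matrix.
#' @param distances kept-match descriptor distances.
#' @param ratioThreshold Lowe ratio used for filtering.
#' @param flag diagnostic flag string.
#' @export
MatchSet <- function(keypointsA, keypointsB, matches, distances,
                     ratioThreshold = NA_real_, flag = "") {
  new("MatchSet", keypointsA = keypointsA, keypointsB = keypointsB,
      matches = matches, distances = distances,
      ratioThreshold = ratioThreshold, flag = flag)
}

# ---- generics & accessors ---------------------------------------------------

#' Number of frames
#' @param x a VideoClip or MaskSequence.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame size (H, W)
#' @param x a VideoClip or MaskSequence.
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))

#' Extract the frame array of a clip
#' @param x a VideoClip.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Extract the mask array of a mask sequence
#' @param x a MaskSequence.
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "VideoClip", function(x) dim(x@frames)[4])
#' @rdname nFrames
#' @export
setMethod("nFrames", "MaskSequence", function(x) dim(x@masks)[3])
#' @rdname frameSize
#' @export
setMethod("frameSize", "VideoClip", function(x) dim(x@frames)[1:2])
#' @rdname frameSize
#' @export
setMethod("frameSize", "MaskSequence", function(x) dim(x@masks)[1:2])
#' @rdname frames
#' @export
setMethod("frames", "VideoClip", function(x) x@frames)
#' @rdname masks
#' @export
setMethod("masks", "MaskSequence", function(x) x@masks)

#' Extract single frames / masks with `[[`
#' @param x a VideoClip or MaskSequence.
#' @param i frame index.
#' @export
setMethod("[[", "VideoClip", function(x, i) x@frames[, , , i, drop = TRUE])
#' @rdname cash-cash-sub-VideoClip-method
#' @export
setMethod("[[", "MaskSequence", function(x, i) x@masks[, , i, drop = TRUE])

setMethod("show", "VideoClip", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VideoClip: %d frame(s) of %d x %d (RGB), range [%.3f, %.3f]\n",
              d[4], d[1], d[2], min(object@frames), max(object@frames)))
})

setMethod("show", "MaskSequence", function(object) {
  d <- dim(object@masks)
  cat(sprintf("MaskSequence: %d mask(s) of %d x %d, %.2f%% hole pixels\n",
              d[3], d[1], d[2], 100 * mean(object@masks)))
})

setMethod("show", "TwoViewScene", function(object) {
  cat(sprintf("TwoViewScene: %d points, |t| = %.3f\n",
              nrow(object@points3d), sqrt(sum(object@translationGT^2))))
})

setMethod("show", "MatchSet", function(object) {
  cat(sprintf("MatchSet: %d / %d keypoints, %d matches (ratio %.2f)%s\n",
              nrow(object@keypointsA), nrow(object@keypointsB),
              nrow(object@matches), object@ratioThreshold,
              if (nzchar(object@flag)) paste0(" [", object@flag, "]") else ""))
})
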