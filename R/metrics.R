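#' Masked mean squared error
#'
#' Mean squared difference over the region of interest, averaged over
#' channels, on the 8-bit scale (values in \code{[0, 1]} are multiplied by
#' \code{peak} before squaring, so identical images differing by 16/255
#' give an MSE of 256).
#'
#' @param ref,test \code{(H, W, 3)} or \code{(H, W)} arrays in
#'   \code{[0, 1]}.
#' @param roi binary matrix (1 = evaluate here); must be nonempty.
#' @param peak intensity scale, default 255.
#' @export
maskedMSE <- function(ref, test, roi, peak = 255) {
  if (sum(roi) == 0) stop("empty region of interest")
  if (!all(dim(ref) == dim(test))) stop("shape mismatch")
  if (length(dim(ref)) == 2L) {dim(ref) <- c(dim(ref), 1L); dim(test) <- dim(ref)}
  sel <- which(roi == 1)
  d2 <- 0
  for (ch in seq_len(dim(ref)[3]))
    d2 <- d2 + mean(((ref[, , ch][sel] - test[, , ch][sel]) * peak)^2)
  d2 / dim(ref)[3]
}

#' Masked peak signal-to-noise ratio
#'
#' \code{10 log10(peak^2 / maskedMSE)} in dB; identical content is capped
#' at 100 dB and flagged via the \code{"capped"} attribute.
#'
#' @inheritParams maskedMSE
#' @param cap dB value reported for zero error.
#' @export
maskedPSNR <- function(ref, test, roi, peak = 255, cap = 100) {
  mse <- maskedMSE(ref, test, roi, peak)
  if (mse == 0) return(structure(cap, capped = TRUE))
  structure(min(cap, 10 * log10(peak^2 / mse)), capped = FALSE)
}

# full-frame SSIM map (grayscale, Gaussian window)
ssimMap <- function(ref, test, window = 11, sigma = 1.5, peak = 1,
                    K1 = 0.01, K2 = 0.03) {
  if (nrow(ref) < window || ncol(ref) < window)
    stop("frame smaller than the SSIM window")
  k <- gaussKernel1d(window, sigma)
  C1 <- (K1 * peak)^2; C2 <- (K2 * peak)^2
  mu1 <- sepConv(ref, k); mu2 <- sepConv(test, k)
  s11 <- sepConv(ref * ref, k) - mu1^2
  s22 <- sepConv(test * test, k) - mu2^2
  s12 <- sepConv(ref * test, k) - mu1 * mu2
  ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
}

#' Masked structural similarity
#'
#' Computes the full-frame SSIM map (Gaussian window, luminance of RGB
#' inputs) and returns its mean over the region of interest, following the
#' convention of evaluating SSIM on the whole frame first so local-window
#' statistics are well defined, then restricting to the ROI.
#'
#' @inheritParams maskedMSE
#' @param window,sigma Gaussian window size (odd) and standard deviation.
#' @export
maskedSSIM <- function(ref, test, roi, window = 11, sigma = 1.5) {
  if (sum(roi) == 0) stop("empty region of interest")
  g1 <- if (length(dim(ref)) == 3L) rgb2gray(ref) else ref
  g2 <- if (length(dim(test)) == 3L) rgb2gray(test) else test
  m <- ssimMap(g1, g2, window, sigma)
  mean(m[roi == 1])
}

#' Two-level metric aggregation (frames within video, then across videos)
#'
#' Computes per-video means of each metric over frames, then the unweighted
#' mean of the per-video means, so videos contribute equally regardless of
#' their frame counts.
#'
#' @param perFrame data.frame with a \code{video} column and one numeric
#'   column per metric.
#' @param maxFramesPerVideo evaluation-time cap on frames per video
#'   (default 927); frames beyond the cap (in row order) are dropped.
#' @return list with \code{perVideo} (data.frame of per-video means),
#'   \code{dataset} (named vector of dataset-level means) and
#'   \code{frameCounts}.
#' @export
aggregateReport <- function(perFrame, maxFramesPerVideo = 927) {
  if (nrow(perFrame) == 0) stop("empty metric table")
  stopifnot("video" %in% names(perFrame))
  keep <- unlist(lapply(split(seq_len(nrow(perFrame)), perFrame$video),
                        function(ix) head(ix, maxFramesPerVideo)))
  perFrame <- perFrame[sort(keep), , drop = FALSE]
  metricCols <- setdiff(names(perFrame), c("video", "frame"))
  vids <- split(perFrame, perFrame$video)
  perVideo <- do.call(rbind, lapply(vids, function(v) {
    row <- as.data.frame(lapply(v[metricCols], mean))
    cbind(data.frame(video = v$video[1], frames = nrow(v)), row)
  }))
  rownames(perVideo) <- NULL
  dataset <- vapply(metricCols, function(mc) mean(perVideo[[mc]]), numeric(1))
  list(perVideo = perVideo, dataset = dataset,
       frameCounts = setNames(perVideo$frames, perVideo$video))
}

#' Masked image-quality report for an inpainted clip
#'
#' Per-frame masked PSNR / SSIM / MSE of a test clip against a reference,
#' evaluated at the ROI of each frame (frames with an empty ROI are
#' skipped).
#'
#' @param ref,test \linkS4class{VideoClip}s.
#' @param roiSeq a \linkS4class{MaskSequence} of evaluation regions.
#' @param video video identifier stored in the output table.
#' @return data.frame with columns video, frame, psnr, ssim, mse.
#' @export
clipMetrics <- function(ref, test, roiSeq, video = "video1") {
  T <- nFrames(ref)
  rows <- list()
  for (t in seq_len(T)) {
    roi <- roiSeq[[t]]
    if (sum(roi) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      video = video, frame = t,
      psnr = as.numeric(maskedPSNR(ref[[t]], test[[t]], roi)),
      ssim = maskedSSIM(ref[[t]], test[[t]], roi),
      mse = maskedMSE(ref[[t]], test[[t]], roi))
  }
  do.call(rbind, rows)
}

#' Disparity error metrics over a region of interest
#'
#' RMS error, endpoint error (mean absolute difference) and Bad3 (percent
#' of pixels whose absolute disparity error strictly exceeds 3 px),
#' evaluated over the ROI intersected with (or minus) the stereo-occlusion
#' mask.
#'
#' @param est,gt disparity matrices (px).
#' @param roi binary evaluation region (e.g. the specularity region).
#' @param occlusionMask optional binary stereo-occlusion mask.
#' @param occlusionMode \code{"exclude"} drops occluded pixels,
#'   \code{"include"} restricts to them, \code{"all"} ignores the mask.
#' @return list with \code{RMS}, \code{EPE}, \code{Bad3} (percent) and
#'   \code{nPixels}.
#' @export
disparityErrors <- function(est, gt, roi, occlusionMask = NULL,
                            occlusionMode = c("all", "exclude", "include")) {
  occlusionMode <- match.arg(occlusionMode)
  eff <- roi == 1
  if (!is.null(occlusionMask)) {
    if (occlusionMode == "exclude") eff <- eff & occlusionMask == 0
    if (occlusionMode == "include") eff <- eff & occlusionMask == 1
  }
  if (sum(eff) == 0) stop("empty effective evaluation region")
  d <- (est - gt)[eff]
  list(RMS = sqrt(mean(d^2)), EPE = mean(abs(d)),
       Bad3 = 100 * mean(abs(d) > 3), nPixels = sum(eff))
}

#' Percentage improvement of an error metric
#'
#' \code{100 (orig - inp) / orig}: positive when inpainting reduced the
#' error.
#'
#' @param metricOrig,metricInp error metric before and after inpainting.
#' @export
percentDelta <- function(metricOrig, metricInp) {
  if (metricOrig == 0)
    return(structure(NA_real_, flag = "undefined: original metric is 0"))
  100 * (metricOrig - metricInp) / metricOrig
}
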