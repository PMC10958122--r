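#' Read a directory of PNG frames into a VideoClip
#'
#' Frames are expected as zero-padded PNG files (\code{00000.png},
#' \code{00001.png}, ...) and are read in lexicographic order.
#'
#' @param dir directory containing the frames.
#' @return a \linkS4class{VideoClip}.
#' @export
readFrames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", dir)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 2L) first <- array(rep(first, 3), c(dim(first), 3))
  H <- dim(first)[1]; W <- dim(first)[2]
  out <- array(0, c(H, W, 3, length(files)))
  out[, , , 1] <- first[, , 1:3]
  for (t in seq_along(files)[-1]) {
    img <- png::readPNG(files[t])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    out[, , , t] <- img[, , 1:3]
  }
  VideoClip(out)
}

#' Write a VideoClip as zero-padded PNG frames
#'
#' @param clip a \linkS4class{VideoClip}.
#' @param dir output directory (created if missing).
#' @param start0 first frame index used in the filenames (default 0).
#' @return the directory, invisibly.
#' @export
writeFrames <- function(clip, dir, start0 = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(nFrames(clip)))
    png::writePNG(clip[[t]], file.path(dir, sprintf("%05d.png",
                                                    start0 + t - 1L)))
  invisible(dir)
}

#' Read a directory of 8-bit mask PNGs (0 = valid, 255 = hole)
#'
#' @param dir mask directory.
#' @return a \linkS4class{MaskSequence}.
#' @export
readMasks <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG masks found in ", dir)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 3L) first <- first[, , 1]
  out <- array(0, c(dim(first), length(files)))
  out[, , 1] <- first > 0.5
  for (t in seq_along(files)[-1]) {
    m <- png::readPNG(files[t])
    if (length(dim(m)) == 3L) m <- m[, , 1]
    out[, , t] <- m > 0.5
  }
  MaskSequence(out)
}

#' Write a MaskSequence as 8-bit PNGs (0 = valid, 255 = hole)
#'
#' @param maskSeq a \linkS4class{MaskSequence}.
#' @param dir output directory.
#' @param start0 first frame index in filenames.
#' @export
writeMasks <- function(maskSeq, dir, start0 = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(nFrames(maskSeq)))
    png::writePNG(maskSeq[[t]], file.path(dir, sprintf("%05d.png",
                                                       start0 + t - 1L)))
  invisible(dir)
}

#' Extract frames from a video container
#'
#' Delegates to an \code{ffmpeg} executable on the PATH; errors cleanly
#' when the file or the executable is missing.  A manifest JSON recording
#' the source, rate and frame count is written next to the frames.
#'
#' @param videoFile input container (e.g. mp4).
#' @param fps extraction rate in frames per second (default 24).
#' @param outDir output frame directory.
#' @return the manifest list, invisibly.
#' @export
extractFrames <- function(videoFile, fps = 24, outDir) {
  if (fps <= 0) stop("fps must be positive")
  if (!file.exists(videoFile)) stop("video file not found: ", videoFile)
  ffmpeg <- Sys.which("ffmpeg")
  if (!nzchar(ffmpeg))
    stop("frame extraction requires an ffmpeg executable on the PATH")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  status <- system2(ffmpeg, c("-y", "-i", shQuote(videoFile),
                              "-vf", sprintf("fps=%g", fps),
                              "-start_number", "0",
                              file.path(outDir, "%05d.png")),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("ffmpeg failed with status ", status)
  n <- length(list.files(outDir, pattern = "\\.png$"))
  manifest <- list(source = videoFile, fps = fps, count = n)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Pipeline run configuration
#'
#' @param outDir root output directory for all stage artifacts.
#' @param seed master seed (fans out to synthesis, training and RANSAC).
#' @param fps frame-extraction rate.
#' @param evalFrameCap evaluation-time cap on frames per video.
#' @param detection a \code{\link{detectionParams}} list.
#' @param pseudo a \code{\link{pseudoGTSpec}} (or NULL for defaults).
#' @param sceneSpec a \code{\link{syntheticSceneSpec}} for the synth stage.
#' @export
runConfig <- function(outDir, seed = 1L, fps = 24, evalFrameCap = 927,
                      detection = detectionParams(), pseudo = NULL,
                      sceneSpec = NULL) {
  if (fps <= 0) stop("fps must be positive")
  structure(list(outDir = outDir, seed = as.integer(seed), fps = fps,
                 evalFrameCap = evalFrameCap, detection = detection,
                 pseudo = pseudo, sceneSpec = sceneSpec),
            class = "RunConfig")
}

#' Run the end-to-end pipeline on a synthetic clip
#'
#' Executes the requested stages in order
#' \code{synth -> detect -> pseudo -> inpaint -> evaluate -> downstream}
#' on a seeded synthetic clip, writing each stage's artifacts (PNG frame
#' and mask directories, JSON reports) under \code{config$outDir} and a
#' provenance log recording the seed and configuration hash.  Stages feed
#' forward: a stage requiring a missing upstream artifact raises an error
#' naming the gap.
#'
#' @param config a \code{\link{runConfig}}.
#' @param stages character vector, subset of \code{c("synth", "detect",
#'   "pseudo", "inpaint", "evaluate", "downstream")}.
#' @param inpainter inpainting method for the inpaint stage:
#'   \code{"diffusion"}, \code{"patch"}, or a \code{GeneratorState}.
#' @return list of stage artifacts including the final \code{report}.
#' @export
runPipeline <- function(config,
                        stages = c("synth", "detect", "pseudo", "inpaint",
                                   "evaluate", "downstream"),
                        inpainter = "diffusion") {
  allStages <- c("synth", "detect", "pseudo", "inpaint", "evaluate",
                 "downstream")
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  out <- list()
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  art <- new.env(parent = emptyenv())
  need <- function(what, stage) {
    v <- art[[what]]
    if (is.null(v))
      stop(sprintf("stage '%s' requires missing upstream artifact '%s'",
                   stage, what))
    v
  }
  if ("synth" %in% stages) {
    spec <- config$sceneSpec %||% syntheticSceneSpec(seed = config$seed)
    syn <- generateClip(spec)
    art$clean <- syn$clean; art$corrupted <- syn$corrupted
    art$gtMasks <- syn$masks
    writeFrames(syn$corrupted, file.path(config$outDir, "frames"))
    writeFrames(syn$clean, file.path(config$outDir, "clean"))
    out$synth <- list(frames = nFrames(syn$corrupted))
  }
  if ("detect" %in% stages) {
    clip <- need("corrupted", "detect")
    det <- detectSpecularClip(clip, config$detection)
    art$detections <- det
    writeMasks(det, file.path(config$outDir, "masks_raw"))
    out$detect <- list(holeFraction = mean(masks(det)))
  }
  if ("pseudo" %in% stages) {
    det <- need("detections", "pseudo")
    ps <- makePseudoMasks(detections = det, spec = config$pseudo)
    art$pseudo <- ps$pseudo; art$segmentation <- ps$segmentation
    writeMasks(ps$pseudo, file.path(config$outDir, "masks_pseudo"))
    jsonlite::write_json(list(translation = ps$translation),
                         file.path(config$outDir, "pseudo_meta.json"),
                         auto_unbox = TRUE)
    out$pseudo <- list(translation = ps$translation,
                       holeFraction = mean(masks(ps$pseudo)))
  }
  if ("inpaint" %in% stages) {
    clip <- need("corrupted", "inpaint")
    pmask <- need("pseudo", "inpaint")
    inp <- if (is.character(inpainter) && inpainter == "diffusion")
      diffusionInpaintClip(clip, pmask)
    else if (is.character(inpainter) && inpainter == "patch")
      temporalPatchInpaint(clip, pmask)
    else inpaintClip(clip, pmask, inpainter)
    art$inpainted <- inp
    writeFrames(inp, file.path(config$outDir, "inpainted"))
    out$inpaint <- list(method = if (is.character(inpainter)) inpainter
                        else "transformer")
  }
  if ("evaluate" %in% stages) {
    ref <- need("corrupted", "evaluate")   # pseudo-GT: texture is known
    test <- need("inpainted", "evaluate")
    roi <- need("pseudo", "evaluate")
    pf <- clipMetrics(ref, test, roi)
    rep <- aggregateReport(pf, config$evalFrameCap)
    art$report <- rep
    jsonlite::write_json(list(perVideo = rep$perVideo,
                              dataset = as.list(rep$dataset)),
                         file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    out$evaluate <- rep
  }
  if ("downstream" %in% stages) {
    test <- need("inpainted", "downstream")
    clip <- need("corrupted", "downstream")
    T <- nFrames(clip)
    gap <- max(1, min(5, T - 1))
    pairs <- cbind(i = seq_len(T - gap), j = seq_len(T - gap) + gap)
    cnt <- function(cl) {
      vapply(seq_len(nrow(pairs)), function(k) {
        ms <- matchFeatures(cl[[pairs[k, 1]]], cl[[pairs[k, 2]]])
        nrow(ms@matches)
      }, numeric(1))
    }
    mOrig <- cnt(clip); mInp <- cnt(test)
    out$downstream <- list(pairs = nrow(pairs),
                           meanMatchesOriginal = mean(mOrig),
                           meanMatchesInpainted = mean(mInp))
    jsonlite::write_json(out$downstream,
                         file.path(config$outDir, "downstream.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  prov <- list(seed = config$seed, fps = config$fps,
               evalFrameCap = config$evalFrameCap, stages = stages)
  jsonlite::write_json(prov, file.path(config$outDir, "provenance.json"),
                       auto_unbox = TRUE)
  out
}
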