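#' Diffusion (harmonic) inpainting of a single frame
#'
#' Replaces hole pixels by the harmonic interpolant of the surrounding
#' valid values (the solution of the Laplace equation with Dirichlet data
#' on the hole boundary and reflecting conditions at the image border).
#' The default solves the sparse linear system exactly; \code{method =
#' "jacobi"} iterates to the requested tolerance instead.
#'
#' @param frame \code{(H, W, 3)} or \code{(H, W)} numeric array.
#' @param mask binary \code{(H, W)} matrix (1 = hole).
#' @param method \code{"direct"} (sparse solve) or \code{"jacobi"}.
#' @param maxIter,tol iteration budget and mean-update tolerance for the
#'   Jacobi path.
#' @return inpainted array of the input shape; valid pixels untouched.
#' @export
diffusionInpaint <- function(frame, mask, method = c("direct", "jacobi"),
                             maxIter = 5000, tol = 1e-8) {
  method <- match.arg(method)
  gray <- length(dim(frame)) == 2L
  if (gray) dim(frame) <- c(dim(frame), 1L)
  H <- dim(frame)[1]; W <- dim(frame)[2]
  if (all(mask == 1)) stop("mask covers the entire frame: no boundary values")
  hole <- which(mask == 1)
  out <- frame
  if (length(hole) == 0) return(if (gray) out[, , 1] else out)
  if (method == "direct") {
    id <- matrix(0L, H, W)
    id[hole] <- seq_along(hole)
    hr <- ((hole - 1) %% H) + 1
    hc <- ((hole - 1) %/% H) + 1
    deg <- numeric(length(hole))
    nbr <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    rhsI <- integer(0); rhsP <- integer(0)
    for (k in 1:4) {
      nr <- hr + nbr[k, 1]; nc <- hc + nbr[k, 2]
      inb <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
      deg <- deg + inb
      nlin <- (nc - 1) * H + nr
      isHole <- inb & mask[pmin(pmax(nlin, 1), H * W)] == 1
      hsel <- which(isHole)
      ii <- c(ii, hsel); jj <- c(jj, id[nlin[hsel]]); xx <- c(xx, rep(-1, length(hsel)))
      ksel <- which(inb & !isHole)
      rhsI <- c(rhsI, ksel); rhsP <- c(rhsP, nlin[ksel])
    }
    n <- length(hole)
    A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                              x = c(deg, xx), dims = c(n, n))
    for (ch in seq_len(dim(frame)[3])) {
      pl <- frame[, , ch]
      b <- numeric(n)
      contrib <- pl[rhsP]
      b <- as.numeric(rowsum(c(contrib, numeric(n)),
                             c(rhsI, seq_len(n)), reorder = TRUE))
      sol <- tryCatch(as.numeric(Matrix::solve(A, b)),
                      error = function(e)
                        stop("hole region has no reachable boundary values"))
      pl[hole] <- sol
      out[, , ch] <- pl
    }
  } else {
    hr <- ((hole - 1) %% H) + 1
    hc <- ((hole - 1) %/% H) + 1
    up <- (pmin(hc, W) - 1) * H + pmax(hr - 1, 1)
    dn <- (hc - 1) * H + pmin(hr + 1, H)
    lf <- (pmax(hc - 1, 1) - 1) * H + hr
    rt <- (pmin(hc + 1, W) - 1) * H + hr
    for (ch in seq_len(dim(frame)[3])) {
      pl <- frame[, , ch]
      pl[hole] <- mean(pl[-hole])
      for (i in seq_len(maxIter)) {
        newv <- (pl[up] + pl[dn] + pl[lf] + pl[rt]) / 4
        delta <- mean(abs(newv - pl[hole]))
        pl[hole] <- newv
        if (delta < tol) break
      }
      out[, , ch] <- pl
    }
  }
  if (gray) out[, , 1] else out
}

#' Diffusion inpainting of a whole clip (frame-wise)
#'
#' @param clip a \linkS4class{VideoClip}.
#' @param maskSeq a \linkS4class{MaskSequence}.
#' @param ... passed to \code{\link{diffusionInpaint}}.
#' @return an inpainted \linkS4class{VideoClip}.
#' @export
diffusionInpaintClip <- function(clip, maskSeq, ...) {
  Y <- frames(clip); M <- masks(maskSeq)
  out <- Y
  for (t in seq_len(nFrames(clip)))
    if (any(M[, , t] == 1))
      out[, , , t] <- diffusionInpaint(Y[, , , t], M[, , t], ...)
  VideoClip(clamp01(out))
}

# summed-area-table box sum of a matrix over a (pr x pc) window centred per
# pixel (window must fit inside the frame; outside returns NA)
boxSumValid <- function(m, pr, pc) {
  H <- nrow(m); W <- ncol(m)
  sat <- apply(apply(m, 2, cumsum), 1, cumsum) # W x H after second apply
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  out <- matrix(NA_real_, H, W)
  rr <- (pr - 1) %/% 2; rc <- (pc - 1) %/% 2
  r0 <- (1 + rr):(H - rr); c0 <- (1 + rc):(W - rc)
  out[r0, c0] <- sat[r0 + rr + 1, c0 + rc + 1] - sat[r0 - rr, c0 + rc + 1] -
    sat[r0 + rr + 1, c0 - rc] + sat[r0 - rr, c0 - rc]
  out
}

#' Greedy spatio-temporal patch-search inpainting
#'
#' Onion-peel exemplar fill: hole patches are processed boundary-first;
#' each is matched against fully-valid candidate patches within a
#' spatio-temporal search window by masked SSD over the known overlap
#' (normalised by overlap size; ties broken by smallest temporal offset,
#' then raster order), and the unknown pixels are copied from the best
#' candidate.
#'
#' @param clip a \linkS4class{VideoClip}.
#' @param maskSeq a \linkS4class{MaskSequence}.
#' @param patch \code{c(pr, pc)} patch size (odd).
#' @param searchTemporal temporal search radius (frames each side).
#' @param searchSpatial spatial search radius (px each side).
#' @param passes number of fill passes; passes after the first re-refine
#'   the filled content using full-patch SSD.
#' @param returnLog if TRUE also return a per-copy log of chosen source
#'   offsets.
#' @return inpainted \linkS4class{VideoClip}, or a list
#'   \code{(clip, log)} when \code{returnLog}.
#' @export
temporalPatchInpaint <- function(clip, maskSeq, patch = c(7, 7),
                                 searchTemporal = 2, searchSpatial = 10,
                                 passes = 1, returnLog = FALSE) {
  Y <- frames(clip); M0 <- masks(maskSeq)
  H <- dim(Y)[1]; W <- dim(Y)[2]; T <- dim(Y)[4]
  pr <- patch[1]; pc <- patch[2]
  if (pr >= H || pc >= W) stop("patch must be smaller than the frame")
  rr <- (pr - 1) %/% 2; rc <- (pc - 1) %/% 2
  offR <- rep(-rr:rr, times = pc); offC <- rep(-rc:rc, each = pr)
  # candidate validity per frame: patch fully valid w.r.t. the ORIGINAL mask
  validCenter <- array(FALSE, c(H, W, T))
  for (t in seq_len(T)) {
    bs <- boxSumValid(M0[, , t], pr, pc)
    validCenter[, , t] <- !is.na(bs) & bs == 0
  }
  out <- Y
  logRows <- list()
  for (pass in seq_len(passes)) {
    work <- M0 # unknown = 1
    if (pass > 1) work <- M0 # refinement recomputes all holes
    for (t in seq_len(T)) {
      wm <- work[, , t]
      if (!any(wm == 1)) next
      guard <- 0
      while (any(wm == 1) && guard < H * W) {
        guard <- guard + 1
        known <- 1 - wm
        # boundary hole pixels: hole with at least one known 4-neighbour
        kpad <- rbind(0, cbind(0, known, 0), 0)
        nbKnown <- kpad[1:H, 2:(W + 1)] + kpad[3:(H + 2), 2:(W + 1)] +
          kpad[2:(H + 1), 1:W] + kpad[2:(H + 1), 3:(W + 2)]
        boundary <- which(wm == 1 & (nbKnown > 0 | pass > 1))
        if (length(boundary) == 0) boundary <- which(wm == 1)
        filledThisRound <- FALSE
        for (lin in boundary) {
          i <- ((lin - 1) %% H) + 1; j <- ((lin - 1) %/% H) + 1
          if (wm[i, j] == 0) next # already filled via an earlier patch
          ic <- pmin(pmax(i, rr + 1), H - rr)
          jc <- pmin(pmax(j, rc + 1), W - rc)
          tr <- ic + offR; tcn <- jc + offC
          tlin <- (tcn - 1) * H + tr
          kmask <- known[tlin] == 1
          if (pass > 1) kmask <- rep(TRUE, length(tlin))
          # gather candidates
          tset <- max(1, t - searchTemporal):min(T, t + searchTemporal)
          best <- NULL
          for (tc in tset[order(abs(tset - t), tset)]) {
            di <- max(rr + 1, ic - searchSpatial):min(H - rr, ic + searchSpatial)
            dj <- max(rc + 1, jc - searchSpatial):min(W - rc, jc + searchSpatial)
            cand <- expand.grid(r = di, c = dj)
            ok <- validCenter[cbind(cand$r, cand$c, tc)]
            if (tc == t) {
              # exclude candidates overlapping the target patch itself
              ok <- ok & (abs(cand$r - ic) > 2 * rr | abs(cand$c - jc) > 2 * rc)
            }
            cand <- cand[ok, , drop = FALSE]
            if (nrow(cand) == 0) next
            # SSD over known overlap, all channels
            ssd <- numeric(nrow(cand))
            for (ch in 1:3) {
              pl <- out[, , ch, tc]
              tv <- out[, , ch, t][tlin]
              cm <- matrix(pl[outer((cand$c - 1) * H + cand$r,
                                    offC * H + offR, "+")],
                           nrow(cand), pr * pc)
              dd <- sweep(cm[, kmask, drop = FALSE], 2, tv[kmask], "-")
              ssd <- ssd + rowSums(dd^2)
            }
            ssd <- ssd / max(1, sum(kmask))
            bi <- which.min(ssd)
            if (is.null(best) || ssd[bi] < best$ssd - 1e-12) {
              best <- list(ssd = ssd[bi], t = tc, r = cand$r[bi],
                           c = cand$c[bi])
            }
            if (!is.null(best) && best$ssd == 0) break
          }
          if (is.null(best)) next
          # copy unknown pixels of the target patch from the best candidate
          slin <- (best$c + offC - 1) * H + (best$r + offR)
          unk <- wm[tlin] == 1
          for (ch in 1:3) {
            pl <- out[, , ch, t]
            src <- out[, , ch, best$t]
            pl[tlin[unk]] <- src[slin[unk]]
            out[, , ch, t] <- pl
          }
          wm[tlin[unk]] <- 0
          filledThisRound <- TRUE
          if (returnLog)
            logRows[[length(logRows) + 1]] <-
              data.frame(pass = pass, frame = t, row = ic, col = jc,
                         srcFrame = best$t, dRow = best$r - ic,
                         dCol = best$c - jc, ssd = best$ssd)
        }
        if (!filledThisRound) {
          if (searchSpatial < max(H, W)) {
            searchSpatial <- searchSpatial * 2 # widen-window fallback
          } else stop("no valid candidate patch found in the search window")
        }
        if (pass > 1) break # refinement visits each boundary set once
      }
      work[, , t] <- wm
    }
  }
  clipOut <- VideoClip(clamp01(out))
  if (returnLog)
    list(clip = clipOut, log = do.call(rbind, logRows))
  else clipOut
}
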