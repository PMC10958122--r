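# Sparse feature matching, dense-flow ingestion, and relative pose
# estimation (five-point essential matrix + RANSAC + chirality), used to
# quantify the effect of inpainting on image correspondence.

# ---- corner detection and binary descriptors --------------------------------

# Harris corners on a grayscale matrix; returns (row, col, response)
harrisCorners <- function(g, maxCorners = 2000, qualityLevel = 0.01,
                          border = 17) {
  H <- nrow(g); W <- ncol(g)
  sh <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(H) + dr, 1), H)
    c <- pmin(pmax(seq_len(W) + dc, 1), W)
    m[r, c]
  }
  Ix <- (sh(g, 0, 1) - sh(g, 0, -1)) / 2
  Iy <- (sh(g, 1, 0) - sh(g, -1, 0)) / 2
  k <- gaussKernel1d(7, 1.5)
  Sxx <- sepConv(Ix * Ix, k); Syy <- sepConv(Iy * Iy, k)
  Sxy <- sepConv(Ix * Iy, k)
  R <- (Sxx * Syy - Sxy^2) - 0.04 * (Sxx + Syy)^2
  # 3x3 non-maximum suppression
  isMax <- R >= sh(R, -1, -1) & R >= sh(R, -1, 0) & R >= sh(R, -1, 1) &
    R >= sh(R, 0, -1) & R >= sh(R, 0, 1) &
    R >= sh(R, 1, -1) & R >= sh(R, 1, 0) & R >= sh(R, 1, 1)
  thr <- qualityLevel * max(R)
  cand <- which(isMax & R > thr & R > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cbind(row = numeric(0), col = numeric(0),
                                    response = numeric(0)))
  ok <- cand[, 1] > border & cand[, 1] <= H - border &
    cand[, 2] > border & cand[, 2] <= W - border
  cand <- cand[ok, , drop = FALSE]
  resp <- R[cand]
  o <- order(resp, decreasing = TRUE)
  sel <- head(o, maxCorners)
  cbind(row = cand[sel, 1], col = cand[sel, 2], response = resp[sel])
}

# fixed BRIEF-style sampling pattern (256 point pairs in a 31x31 patch),
# generated once from a constant seed so descriptors are reproducible
briefPattern <- function() {
  hit <- .idxCache[["briefPattern"]]
  if (!is.null(hit)) return(hit)
  p <- withSeed(90210L, {
    s <- 31 / 5
    m <- matrix(round(pmin(pmax(rnorm(256 * 4, 0, s), -15), 15)), 256, 4)
    colnames(m) <- c("r1", "c1", "r2", "c2")
    m
  })
  .idxCache[["briefPattern"]] <- p
  p
}

# binary descriptors at keypoints (row, col) of a smoothed gray image
briefDescriptors <- function(g, kp) {
  gs <- sepConv(g, gaussKernel1d(9, 2))
  pat <- briefPattern()
  H <- nrow(g)
  n <- nrow(kp)
  D <- matrix(0L, n, 256)
  for (b in 1:256) {
    i1 <- (kp[, 2] + pat[b, "c1"] - 1) * H + kp[, 1] + pat[b, "r1"]
    i2 <- (kp[, 2] + pat[b, "c2"] - 1) * H + kp[, 1] + pat[b, "r2"]
    D[, b] <- (gs[i1] < gs[i2]) * 1L
  }
  D
}

#' Detect and match sparse features between two frames
#'
#' Corner detection (Harris response, non-maximum suppression), binary
#' intensity-comparison descriptors on the smoothed image, brute-force
#' Hamming matching, and Lowe's ratio test (a match is kept when its best
#' distance is below \code{ratio} times its second-best).
#'
#' @param frameA,frameB \code{(H, W, 3)} RGB or \code{(H, W)} grayscale
#'   arrays in \code{[0, 1]}.
#' @param maxFeatures maximum keypoints per frame.
#' @param ratio Lowe ratio threshold (default 0.75).
#' @param qualityLevel corner-response threshold relative to the maximum.
#' @return a \linkS4class{MatchSet}; keypoints are in (x, y) = (col, row)
#'   pixel coordinates.
#' @export
matchFeatures <- function(frameA, frameB, maxFeatures = 2000, ratio = 0.75,
                          qualityLevel = 0.01) {
  gA <- if (length(dim(frameA)) == 3L) rgb2gray(frameA) else frameA
  gB <- if (length(dim(frameB)) == 3L) rgb2gray(frameB) else frameB
  kpA <- harrisCorners(gA, maxFeatures, qualityLevel)
  kpB <- harrisCorners(gB, maxFeatures, qualityLevel)
  empty <- function(flag) MatchSet(
    keypointsA = cbind(x = kpA[, 2], y = kpA[, 1]),
    keypointsB = cbind(x = kpB[, 2], y = kpB[, 1]),
    matches = matrix(0L, 0, 2), distances = numeric(0),
    ratioThreshold = ratio, flag = flag)
  if (nrow(kpA) < 2 || nrow(kpB) < 2) return(empty("too few keypoints"))
  DA <- briefDescriptors(gA, kpA)
  DB <- briefDescriptors(gB, kpB)
  # Hamming distances via two matrix products
  Dist <- DA %*% (1 - t(DB)) + (1 - DA) %*% t(DB)
  best <- max.col(-Dist, ties.method = "first")
  d1 <- Dist[cbind(seq_len(nrow(Dist)), best)]
  Dist2 <- Dist
  Dist2[cbind(seq_len(nrow(Dist)), best)] <- Inf
  d2 <- apply(Dist2, 1, min)
  keep <- which(d1 < ratio * d2)
  if (length(keep) == 0) return(empty("no matches passed the ratio test"))
  MatchSet(keypointsA = cbind(x = kpA[, 2], y = kpA[, 1]),
           keypointsB = cbind(x = kpB[, 2], y = kpB[, 1]),
           matches = cbind(keep, best[keep]), distances = d1[keep],
           ratioThreshold = ratio, flag = "")
}

#' Convert a dense flow field to a correspondence set
#'
#' Subsamples the flow on a regular grid and emits correspondences
#' \code{(p, p + flow(p))} for valid, in-bounds grid points.
#'
#' @param flow \code{(H, W, 2)} array; \code{flow[,,1]} is the horizontal
#'   (x) displacement, \code{flow[,,2]} the vertical (y) displacement.
#' @param stride grid spacing in px (must be smaller than the frame).
#' @param validityMask optional binary matrix; grid points with 0 are
#'   dropped.
#' @return a \linkS4class{MatchSet}.
#' @export
flowToMatches <- function(flow, stride = 8, validityMask = NULL) {
  H <- dim(flow)[1]; W <- dim(flow)[2]
  if (stride >= min(H, W)) stop("stride must be smaller than the frame")
  rs <- seq(1 + stride %/% 2, H, by = stride)
  cs <- seq(1 + stride %/% 2, W, by = stride)
  g <- expand.grid(r = rs, c = cs)
  u <- flow[, , 1][cbind(g$r, g$c)]
  v <- flow[, , 2][cbind(g$r, g$c)]
  xb <- g$c + u; yb <- g$r + v
  ok <- xb >= 1 & xb <= W & yb >= 1 & yb <= H
  if (!is.null(validityMask)) ok <- ok & validityMask[cbind(g$r, g$c)] == 1
  kA <- cbind(x = g$c[ok], y = g$r[ok])
  kB <- cbind(x = xb[ok], y = yb[ok])
  n <- nrow(kA)
  MatchSet(keypointsA = kA, keypointsB = kB,
           matches = cbind(seq_len(n), seq_len(n)),
           distances = numeric(n), ratioThreshold = NA_real_,
           flag = if (n == 0) "empty" else "")
}

# ---- five-point essential matrix -------------------------------------------

# polynomial arithmetic over fixed monomial bases in (x, y, z):
#  linear: (x, y, z, 1)
#  quadratic: (x2, xy, y2, xz, yz, z2, x, y, z, 1)
#  cubic: (x3, x2y, xy2, y3, x2z, xyz, y2z, xz2, yz2, z3,
#          x2, xy, y2, xz, yz, z2, x, y, z, 1)
polyMulLL <- function(a, b) {
  c(a[1] * b[1],                     # x2
    a[1] * b[2] + a[2] * b[1],       # xy
    a[2] * b[2],                     # y2
    a[1] * b[3] + a[3] * b[1],       # xz
    a[2] * b[3] + a[3] * b[2],       # yz
    a[3] * b[3],                     # z2
    a[1] * b[4] + a[4] * b[1],       # x
    a[2] * b[4] + a[4] * b[2],       # y
    a[3] * b[4] + a[4] * b[3],       # z
    a[4] * b[4])                     # 1
}

polyMulQL <- function(q, l) {
  out <- numeric(20)
  # cubic monomial indices
  X3 <- 1; X2Y <- 2; XY2 <- 3; Y3 <- 4; X2Z <- 5; XYZ <- 6; Y2Z <- 7
  XZ2 <- 8; YZ2 <- 9; Z3 <- 10
  X2 <- 11; XY <- 12; Y2 <- 13; XZ <- 14; YZ <- 15; Z2 <- 16
  X <- 17; Yc <- 18; Z <- 19; ONE <- 20
  add <- function(i, v) out[i] <<- out[i] + v
  # q entries: 1 x2, 2 xy, 3 y2, 4 xz, 5 yz, 6 z2, 7 x, 8 y, 9 z, 10 1
  # times l = (lx, ly, lz, lc)
  add(X3,  q[1] * l[1]); add(X2Y, q[1] * l[2]); add(X2Z, q[1] * l[3]); add(X2, q[1] * l[4])
  add(X2Y, q[2] * l[1]); add(XY2, q[2] * l[2]); add(XYZ, q[2] * l[3]); add(XY, q[2] * l[4])
  add(XY2, q[3] * l[1]); add(Y3,  q[3] * l[2]); add(Y2Z, q[3] * l[3]); add(Y2, q[3] * l[4])
  add(X2Z, q[4] * l[1]); add(XYZ, q[4] * l[2]); add(XZ2, q[4] * l[3]); add(XZ, q[4] * l[4])
  add(XYZ, q[5] * l[1]); add(Y2Z, q[5] * l[2]); add(YZ2, q[5] * l[3]); add(YZ, q[5] * l[4])
  add(XZ2, q[6] * l[1]); add(YZ2, q[6] * l[2]); add(Z3,  q[6] * l[3]); add(Z2, q[6] * l[4])
  add(X2,  q[7] * l[1]); add(XY,  q[7] * l[2]); add(XZ,  q[7] * l[3]); add(X,  q[7] * l[4])
  add(XY,  q[8] * l[1]); add(Y2,  q[8] * l[2]); add(YZ,  q[8] * l[3]); add(Yc, q[8] * l[4])
  add(XZ,  q[9] * l[1]); add(YZ,  q[9] * l[2]); add(Z2,  q[9] * l[3]); add(Z,  q[9] * l[4])
  add(X,  q[10] * l[1]); add(Yc, q[10] * l[2]); add(Z,  q[10] * l[3]); add(ONE, q[10] * l[4])
  out
}

#' Five-point essential matrix solver
#'
#' Minimal solver for the calibrated relative-pose problem: given five
#' correspondences in normalised image coordinates, returns all real
#' essential matrices consistent with them.  The null space of the 5 x 9
#' epipolar system gives \code{E = x E1 + y E2 + z E3 + E4}; imposing
#' \code{det(E) = 0} and the trace constraint
#' \code{2 E E' E - tr(E E') E = 0} yields ten cubic equations whose
#' solutions are extracted from the eigen-decomposition of the action
#' matrix of multiplication by z in the quotient-ring basis of degree-two
#' monomials.
#'
#' @param x1,x2 5 x 2 matrices of normalised coordinates in view 1 / 2.
#' @return list of 3 x 3 essential matrices (possibly empty).
#' @export
fivePointEssential <- function(x1, x2) {
  if (nrow(x1) != 5 || nrow(x2) != 5) stop("exactly five correspondences required")
  A <- matrix(0, 5, 9)
  for (i in 1:5) {
    p <- c(x1[i, ], 1); q <- c(x2[i, ], 1)
    A[i, ] <- c(q[1] * p, q[2] * p, q[3] * p)
  }
  ns <- svd(A, nv = 9)$v[, 6:9]
  Es <- lapply(1:4, function(k) matrix(ns[, k], 3, 3, byrow = TRUE))
  # linear form of each E entry: coefficients of (x, y, z, 1)
  L <- array(0, c(3, 3, 4))
  for (k in 1:4) L[, , k] <- Es[[k]]
  lin <- function(i, j) c(L[i, j, 1], L[i, j, 2], L[i, j, 3], L[i, j, 4])
  M <- matrix(0, 10, 20)
  # det(E) = 0 via cofactor expansion along the first row
  det3 <- function() {
    c11 <- polyMulLL(lin(2, 2), lin(3, 3)) - polyMulLL(lin(2, 3), lin(3, 2))
    c12 <- polyMulLL(lin(2, 1), lin(3, 3)) - polyMulLL(lin(2, 3), lin(3, 1))
    c13 <- polyMulLL(lin(2, 1), lin(3, 2)) - polyMulLL(lin(2, 2), lin(3, 1))
    polyMulQL(c11, lin(1, 1)) - polyMulQL(c12, lin(1, 2)) +
      polyMulQL(c13, lin(1, 3))
  }
  M[1, ] <- det3()
  # trace constraint: 2 E E' E - tr(E E') E = 0
  EEt <- array(0, c(3, 3, 10)) # quadratic entries of E E'
  for (i in 1:3) for (j in 1:3) {
    q <- numeric(10)
    for (k in 1:3) q <- q + polyMulLL(lin(i, k), lin(j, k))
    EEt[i, j, ] <- q
  }
  trq <- EEt[1, 1, ] + EEt[2, 2, ] + EEt[3, 3, ]
  r <- 2
  for (i in 1:3) for (j in 1:3) {
    cub <- numeric(20)
    for (k in 1:3) cub <- cub + polyMulQL(2 * EEt[i, k, ], lin(k, j))
    cub <- cub - polyMulQL(trq, lin(i, j))
    M[r, ] <- cub
    r <- r + 1
  }
  M3 <- M[, 1:10]; M2 <- M[, 11:20]
  Nrm <- tryCatch(-solve(M3, M2), error = function(e) NULL)
  if (is.null(Nrm)) return(list())
  # action matrix of multiplication by z in basis
  # B = (x2, xy, y2, xz, yz, z2, x, y, z, 1)
  Az <- matrix(0, 10, 10)
  Az[, 1] <- Nrm[5, ]  # z * x2  = x2z
  Az[, 2] <- Nrm[6, ]  # z * xy  = xyz
  Az[, 3] <- Nrm[7, ]  # z * y2  = y2z
  Az[, 4] <- Nrm[8, ]  # z * xz  = xz2
  Az[, 5] <- Nrm[9, ]  # z * yz  = yz2
  Az[, 6] <- Nrm[10, ] # z * z2  = z3
  Az[4, 7] <- 1        # z * x   = xz
  Az[5, 8] <- 1        # z * y   = yz
  Az[6, 9] <- 1        # z * z   = z2
  Az[9, 10] <- 1       # z * 1   = z
  eg <- eigen(t(Az))
  sols <- list()
  for (k in 1:10) {
    v <- eg$vectors[, k]
    if (abs(v[10]) < 1e-12) next
    v <- v / v[10]
    if (max(abs(Im(v))) > 1e-6 * max(1, max(abs(Re(v))))) next
    x <- Re(v[7]); y <- Re(v[8]); z <- Re(v[9])
    E <- x * Es[[1]] + y * Es[[2]] + z * Es[[3]] + Es[[4]]
    nE <- sqrt(sum(E^2))
    if (!is.finite(nE) || nE < 1e-12) next
    sols[[length(sols) + 1]] <- E / nE
  }
  # deduplicate (up to sign)
  if (length(sols) > 1) {
    keep <- rep(TRUE, length(sols))
    for (i in seq_along(sols)) if (keep[i]) for (j in seq_along(sols)) {
      if (j <= i || !keep[j]) next
      if (min(max(abs(sols[[i]] - sols[[j]])),
              max(abs(sols[[i]] + sols[[j]]))) < 1e-8) keep[j] <- FALSE
    }
    sols <- sols[keep]
  }
  sols
}

# Sampson distance of correspondences under E (normalised coordinates)
sampsonError <- function(E, x1, x2) {
  n <- nrow(x1)
  X1 <- rbind(t(x1), 1); X2 <- rbind(t(x2), 1)
  Ex1 <- E %*% X1
  Etx2 <- t(E) %*% X2
  num <- colSums(X2 * Ex1)
  num^2 / (Ex1[1, ]^2 + Ex1[2, ]^2 + Etx2[1, ]^2 + Etx2[2, ]^2)
}

# linear (eight-point style) essential fit on >= 8 normalised matches,
# projected onto the essential manifold
linearEssential <- function(x1, x2) {
  n <- nrow(x1)
  A <- matrix(0, n, 9)
  for (i in seq_len(n)) {
    p <- c(x1[i, ], 1); q <- c(x2[i, ], 1)
    A[i, ] <- c(q[1] * p, q[2] * p, q[3] * p)
  }
  e <- svd(A, nv = 9)$v[, 9]
  E <- matrix(e, 3, 3, byrow = TRUE)
  s <- svd(E)
  s$u %*% diag(c(1, 1, 0)) %*% t(s$v)
}

# linear DLT triangulation; returns depths of each point in both views
# (camera 1 at the origin, camera 2 at (R, t))
triangulateDepths <- function(R, t, x1, x2) {
  n <- nrow(x1)
  z1 <- numeric(n); z2 <- numeric(n)
  P1 <- cbind(diag(3), 0)
  P2 <- cbind(R, t)
  for (i in seq_len(n)) {
    A <- rbind(x1[i, 1] * P1[3, ] - P1[1, ],
               x1[i, 2] * P1[3, ] - P1[2, ],
               x2[i, 1] * P2[3, ] - P2[1, ],
               x2[i, 2] * P2[3, ] - P2[2, ])
    X <- svd(A, nv = 4)$v[, 4]
    if (abs(X[4]) < 1e-12) next
    X <- X[1:3] / X[4]
    z1[i] <- X[3]
    z2[i] <- (R %*% X + t)[3]
  }
  cbind(z1, z2)
}

# decompose E into the four (R, t) hypotheses
decomposeEssential <- function(E) {
  s <- svd(E)
  U <- s$u; V <- s$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  R1 <- U %*% W %*% t(V)
  R2 <- U %*% t(W) %*% t(V)
  t1 <- U[, 3]
  list(list(R = R1, t = t1), list(R = R1, t = -t1),
       list(R = R2, t = t1), list(R = R2, t = -t1))
}

#' Relative pose from a correspondence set
#'
#' Essential-matrix estimation with the five-point minimal solver inside
#' RANSAC (Sampson-distance inlier test), linear refit on the consensus
#' set, decomposition into the four pose hypotheses, and selection by the
#' chirality check (most triangulated points in front of both cameras).
#' The translation is returned unit-norm.  A rotation-only (baseline-free)
#' configuration is detected by checking whether a pure rotation aligned
#' with Procrustes already explains the bearing vectors to within the
#' inlier threshold; such results carry \code{degenerate = TRUE}.
#'
#' @param matchSet a \linkS4class{MatchSet} (or a list with matrices
#'   \code{ptsA}, \code{ptsB} of matched pixel coordinates).
#' @param intrinsics 3 x 3 calibration matrix.
#' @param thresholdPx RANSAC inlier threshold in pixels.
#' @param confidence RANSAC confidence for adaptive stopping.
#' @param maxIter maximum RANSAC iterations.
#' @param seed RANSAC sampling seed.
#' @return list with \code{R}, \code{t} (unit), \code{inliers} (count),
#'   \code{inlierIdx}, \code{E}, and \code{degenerate}.
#' @export
estimateRelativePose <- function(matchSet, intrinsics, thresholdPx = 1.0,
                                 confidence = 0.999, maxIter = 2000,
                                 seed = 1L) {
  if (is(matchSet, "MatchSet")) {
    m <- matchSet@matches
    pA <- matchSet@keypointsA[m[, 1], , drop = FALSE]
    pB <- matchSet@keypointsB[m[, 2], , drop = FALSE]
  } else {
    pA <- matchSet$ptsA; pB <- matchSet$ptsB
  }
  n <- nrow(pA)
  if (n < 5) stop("at least 5 matches required for pose estimation")
  Kinv <- solve(intrinsics)
  toNorm <- function(p) {
    h <- Kinv %*% rbind(t(p), 1)
    t(h[1:2, , drop = FALSE] / h[3, ])
  }
  x1 <- toNorm(pA); x2 <- toNorm(pB)
  f <- mean(abs(c(intrinsics[1, 1], intrinsics[2, 2])))
  thr <- (thresholdPx / f)^2
  # rotation-only degeneracy: does a pure rotation explain the bearings?
  b1 <- rbind(t(x1), 1); b1 <- sweep(b1, 2, sqrt(colSums(b1^2)), "/")
  b2 <- rbind(t(x2), 1); b2 <- sweep(b2, 2, sqrt(colSums(b2^2)), "/")
  sv <- svd(b2 %*% t(b1))
  R0 <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  resid <- acos(pmin(1, colSums(b2 * (R0 %*% b1))))
  degenerate <- median(resid) < 3 * sqrt(thr)
  withSeed(seed, {
    bestE <- NULL; bestInl <- -1; bestIdx <- NULL
    it <- 0; needed <- maxIter
    while (it < min(needed, maxIter)) {
      it <- it + 1
      sel <- sample.int(n, 5)
      cands <- tryCatch(fivePointEssential(x1[sel, ], x2[sel, ]),
                        error = function(e) list())
      for (E in cands) {
        err <- sampsonError(E, x1, x2)
        inl <- which(err < thr)
        if (length(inl) > bestInl) {
          bestInl <- length(inl); bestE <- E; bestIdx <- inl
          w <- max(length(inl) / n, 1e-9)
          needed <- log(1 - confidence) / log(1 - w^5 + 1e-12)
        }
      }
    }
    if (is.null(bestE)) {
      if (degenerate) {
        # baseline-free configuration: report the Procrustes rotation and a
        # placeholder direction, flagged so callers can exclude the pair
        return(list(R = R0, t = c(0, 0, 1), inliers = sum(resid < sqrt(thr)),
                    inlierIdx = which(resid < sqrt(thr)), E = NULL,
                    degenerate = TRUE))
      }
      stop("RANSAC failed to find any essential matrix")
    }
    if (length(bestIdx) >= 8) {
      Eref <- linearEssential(x1[bestIdx, , drop = FALSE],
                              x2[bestIdx, , drop = FALSE])
      err <- sampsonError(Eref, x1, x2)
      inl <- which(err < thr)
      if (length(inl) >= bestInl) {bestE <- Eref; bestIdx <- inl}
    }
    # chirality: pick the hypothesis with most points in front of both views
    hyp <- decomposeEssential(bestE)
    bestHyp <- NULL; bestPos <- -1
    sub <- bestIdx
    if (length(sub) > 50) sub <- sub[round(seq(1, length(sub), length.out = 50))]
    for (h in hyp) {
      zz <- triangulateDepths(h$R, h$t, x1[sub, , drop = FALSE],
                              x2[sub, , drop = FALSE])
      npos <- sum(zz[, 1] > 0 & zz[, 2] > 0)
      if (npos > bestPos) {bestPos <- npos; bestHyp <- h}
    }
    list(R = bestHyp$R, t = unitize(bestHyp$t), inliers = length(bestIdx),
         inlierIdx = bestIdx, E = bestE, degenerate = degenerate)
  })
}

#' Relative rotation error (geodesic angle)
#'
#' @param Rest,Rgt 3 x 3 rotation matrices.
#' @param tolOrtho orthonormality tolerance.
#' @return angle in degrees.
#' @export
rotationError <- function(Rest, Rgt, tolOrtho = 1e-6) {
  for (R in list(Rest, Rgt))
    if (max(abs(crossprod(R) - diag(3))) > tolOrtho)
      stop("input is not orthonormal within tolerance")
  ct <- (sum(diag(Rest %*% t(Rgt))) - 1) / 2
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Relative translation direction error
#'
#' Angle between the unit translation directions, folded over the sign
#' ambiguity of the essential-matrix decomposition:
#' \code{min(theta, 180 - theta)}.
#'
#' @param tEst,tGt translation vectors (any nonzero scale).
#' @return angle in degrees, in \code{[0, 90]}.
#' @export
translationError <- function(tEst, tGt) {
  a <- unitize(tEst); b <- unitize(tGt)
  th <- acos(pmin(pmax(sum(a * b), -1), 1)) * 180 / pi
  min(th, 180 - th)
}

#' Frame pairs from a moving window
#'
#' Pairs \code{(i, i + window)} for \code{i = 1 ... nFrames - window}
#' (1-based, stride 1 by default).
#'
#' @param nFrames sequence length.
#' @param window frame separation (default 20).
#' @param stride step between successive window starts.
#' @return integer matrix with columns \code{i}, \code{j}; zero rows (with
#'   attribute \code{flag}) when the sequence is too short.
#' @export
windowPairs <- function(nFrames, window = 20, stride = 1) {
  if (nFrames <= window) {
    out <- cbind(i = integer(0), j = integer(0))
    attr(out, "flag") <- "sequence shorter than window"
    return(out)
  }
  i <- seq(1, nFrames - window, by = stride)
  cbind(i = i, j = i + window)
}

#' Paired summary statistics of pose-error differences
#'
#' For each metric (RTE, RRE, inliers), forms the per-pair difference
#' \code{orig - inp} (positive = inpainting reduced the error) and reports
#' Min, Max, Mean, 25th percentile, Median, 75th percentile and IQR
#' (linear-interpolation quantiles), plus the mean per-pair signed
#' relative difference in percent (pairs with a zero original value are
#' excluded from the relative mean).
#'
#' @param errorsOrig,errorsInp data.frames with columns \code{pair},
#'   \code{RTE}, \code{RRE}, \code{inliers}, paired by identical
#'   \code{pair} values.
#' @return data.frame with one row per metric.
#' @export
summarizePoseErrors <- function(errorsOrig, errorsInp) {
  if (!identical(sort(errorsOrig$pair), sort(errorsInp$pair)))
    stop("pair sets differ between the two error tables")
  o <- errorsOrig[order(errorsOrig$pair), ]
  i <- errorsInp[order(errorsInp$pair), ]
  one <- function(metric) {
    d <- o[[metric]] - i[[metric]]
    q <- quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    rel <- o[[metric]] != 0
    data.frame(metric = metric, min = min(d), max = max(d), mean = mean(d),
               p25 = q[1], median = q[2], p75 = q[3], iqr = q[3] - q[1],
               meanRelPct = if (any(rel))
                 mean(100 * d[rel] / o[[metric]][rel]) else NA_real_)
  }
  do.call(rbind, lapply(c("RTE", "RRE", "inliers"), one))
}

# ---- simple pyramidal dense flow (test-scale provider) ----------------------

downsample2 <- function(m) {
  H <- 2 * (nrow(m) %/% 2); W <- 2 * (ncol(m) %/% 2)
  m <- m[seq_len(H), seq_len(W)]
  (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
     m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)]) / 4
}

#' Dense optical flow by pyramidal Lucas-Kanade warping
#'
#' A compact coarse-to-fine dense flow estimator used as the in-repo
#' correspondence provider for tests and demonstrations; production flow
#' networks are treated as pluggable external providers.
#'
#' @param g1,g2 grayscale matrices in \code{[0, 1]} (RGB arrays are
#'   converted).
#' @param levels pyramid levels (default chosen from the frame size).
#' @param window odd local window for the least-squares system.
#' @param iters warp iterations per level.
#' @return \code{(H, W, 2)} flow array; \code{[,,1]} horizontal,
#'   \code{[,,2]} vertical displacement.
#' @export
estimateFlow <- function(g1, g2, levels = NULL, window = 9, iters = 3) {
  if (length(dim(g1)) == 3L) g1 <- rgb2gray(g1)
  if (length(dim(g2)) == 3L) g2 <- rgb2gray(g2)
  levels <- levels %||% max(1, floor(log2(min(dim(g1)) / 12)))
  p1 <- list(g1); p2 <- list(g2)
  for (l in seq_len(levels - 1)) {
    p1[[l + 1]] <- downsample2(p1[[l]])
    p2[[l + 1]] <- downsample2(p2[[l]])
  }
  u <- matrix(0, nrow(p1[[levels]]), ncol(p1[[levels]]))
  v <- u
  k <- gaussKernel1d(window, window / 4)
  for (l in rev(seq_len(levels))) {
    I1 <- p1[[l]]; I2 <- p2[[l]]
    H <- nrow(I1); W <- ncol(I1)
    if (nrow(u) != H) {
      u <- 2 * u[rep(seq_len(nrow(u)), each = 2), rep(seq_len(ncol(u)), each = 2)]
      v <- 2 * v[rep(seq_len(nrow(v)), each = 2), rep(seq_len(ncol(v)), each = 2)]
      u <- u[seq_len(H), seq_len(W)]; v <- v[seq_len(H), seq_len(W)]
    }
    gr <- matrix(seq_len(H), H, W); gc <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (itr in seq_len(iters)) {
      I2w <- matrix(bilinearSample(I2, as.vector(gr + v), as.vector(gc + u)),
                    H, W)
      sh <- function(m, dr, dc) {
        r <- pmin(pmax(seq_len(H) + dr, 1), H)
        c <- pmin(pmax(seq_len(W) + dc, 1), W)
        m[r, c]
      }
      Ix <- (sh(I2w, 0, 1) - sh(I2w, 0, -1)) / 2
      Iy <- (sh(I2w, 1, 0) - sh(I2w, -1, 0)) / 2
      It <- I2w - I1
      Sxx <- sepConv(Ix * Ix, k); Syy <- sepConv(Iy * Iy, k)
      Sxy <- sepConv(Ix * Iy, k)
      Sxt <- sepConv(Ix * It, k); Syt <- sepConv(Iy * It, k)
      det <- Sxx * Syy - Sxy^2
      det[abs(det) < 1e-9] <- Inf
      du <- (-Syy * Sxt + Sxy * Syt) / det
      dv <- (Sxy * Sxt - Sxx * Syt) / det
      u <- u + pmin(pmax(du, -2), 2)
      v <- v + pmin(pmax(dv, -2), 2)
    }
  }
  out <- array(0, c(nrow(g1), ncol(g1), 2))
  out[, , 1] <- u; out[, , 2] <- v
  out
}
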