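# Coarse-to-fine registration of drifted acquisitions onto their reference:
# a keypoint-based global homography stage followed by dense optical flow.

registrationFailure <- function(message, nMatches) {
  stop(structure(
    class = c("registrationFailure", "error", "condition"),
    list(message = message, call = sys.call(-1), nMatches = nMatches)
  ))
}

sobelGradients <- function(img) {
  kd <- c(-1, 0, 1) / 2
  ks <- c(1, 2, 1) / 4
  list(
    gx = sepConvolve(img, ks, kd),
    gy = sepConvolve(img, kd, ks)
  )
}

# Shi-Tomasi corners (minimum eigenvalue of the structure tensor) with 3x3
# non-maximum suppression and quadratic subpixel refinement
detectCorners <- function(img, maxCorners = 700, qualityLevel = 0.01,
                          margin = 16L) {
  g <- sobelGradients(img)
  sxx <- gaussianBlur(g$gx * g$gx, 2)
  syy <- gaussianBlur(g$gy * g$gy, 2)
  sxy <- gaussianBlur(g$gx * g$gy, 2)
  tr2 <- (sxx + syy) / 2
  resp <- tr2 - sqrt(((sxx - syy) / 2)^2 + sxy^2)
  h <- nrow(img); w <- ncol(img)
  # 3x3 max filter
  mx <- resp
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    sh <- resp[clamp(seq_len(h) + dy, 1L, h), clamp(seq_len(w) + dx, 1L, w)]
    mx <- pmax(mx, sh)
  }
  ok <- resp >= mx & resp > qualityLevel * max(resp)
  ok[seq_len(min(margin, h)), ] <- FALSE; ok[(h - margin + 1):h, ] <- FALSE
  ok[, seq_len(min(margin, w))] <- FALSE; ok[, (w - margin + 1):w] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0) return(cbind(y = numeric(0), x = numeric(0)))
  ord <- order(resp[idx], decreasing = TRUE)
  idx <- idx[ord[seq_len(min(maxCorners, length(ord)))], , drop = FALSE]
  # per-axis parabola fit for subpixel position
  refine <- function(r, c) {
    dy <- dx <- 0
    if (r > 1 && r < h) {
      a <- resp[r - 1, c]; b <- resp[r, c]; d <- resp[r + 1, c]
      den <- a - 2 * b + d
      if (abs(den) > 1e-12) dy <- clamp(0.5 * (a - d) / den, -0.5, 0.5)
    }
    if (c > 1 && c < w) {
      a <- resp[r, c - 1]; b <- resp[r, c]; d <- resp[r, c + 1]
      den <- a - 2 * b + d
      if (abs(den) > 1e-12) dx <- clamp(0.5 * (a - d) / den, -0.5, 0.5)
    }
    c(dy, dx)
  }
  off <- t(vapply(seq_len(nrow(idx)),
                  function(i) refine(idx[i, 1], idx[i, 2]), numeric(2)))
  cbind(y = idx[, 1] + off[, 1], x = idx[, 2] + off[, 2])
}

# fixed binary-descriptor sampling pattern (256 point pairs), deterministic
briefPattern <- local({
  pat <- NULL
  function(patchR = 12) {
    if (is.null(pat)) {
      pat <<- withLocalSeed(1234L, {
        m <- matrix(stats::rnorm(256 * 4, sd = patchR / 2.5), 256, 4)
        clamp(m, -patchR, patchR)
      })
    }
    pat
  }
})

# oriented BRIEF descriptors at the given keypoints; orientation from the
# intensity centroid of a disc around the corner
briefDescriptors <- function(img, pts, patchR = 12) {
  n <- nrow(pts)
  if (n == 0) return(matrix(FALSE, 0, 256))
  sm <- gaussianBlur(img, 2)
  r <- 7L
  dy <- rep(-r:r, times = 2 * r + 1)
  dx <- rep(-r:r, each = 2 * r + 1)
  disc <- dy^2 + dx^2 <= r^2
  dy <- dy[disc]; dx <- dx[disc]
  pat <- briefPattern(patchR)
  desc <- matrix(FALSE, n, 256)
  for (i in seq_len(n)) {
    y <- pts[i, 1]; x <- pts[i, 2]
    v <- bilinearSample(sm, y + dy, x + dx)
    theta <- atan2(sum(dy * v), sum(dx * v))
    ct <- cos(theta); st <- sin(theta)
    # rotate the sampling pairs by the patch orientation
    y1 <- y + st * pat[, 1] + ct * pat[, 2]
    x1 <- x + ct * pat[, 1] - st * pat[, 2]
    y2 <- y + st * pat[, 3] + ct * pat[, 4]
    x2 <- x + ct * pat[, 3] - st * pat[, 4]
    desc[i, ] <- bilinearSample(sm, y1, x1) < bilinearSample(sm, y2, x2)
  }
  desc
}

# Hamming matching with Lowe ratio test
matchDescriptors <- function(d1, d2, ratio = 0.75) {
  if (nrow(d1) == 0 || nrow(d2) < 2) return(cbind(i = integer(0), j = integer(0)))
  m1 <- d1 * 1; m2 <- d2 * 1
  ham <- m1 %*% (1 - t(m2)) + (1 - m1) %*% t(m2)
  best <- max.col(-ham, ties.method = "first")
  bestD <- ham[cbind(seq_len(nrow(ham)), best)]
  ham2 <- ham
  ham2[cbind(seq_len(nrow(ham)), best)] <- Inf
  secondD <- apply(ham2, 1, min)
  keep <- bestD < ratio * secondD
  cbind(i = which(keep), j = best[keep])
}

# normalized direct linear transform homography from point correspondences
# pts given as (x, y); returns 3x3 H with H %*% (x, y, 1) ~ (x', y', 1)
dltHomography <- function(p1, p2) {
  normalize <- function(p) {
    mu <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, mu)^2))
    s <- sqrt(2) / max(mean(d), 1e-12)
    Tm <- rbind(c(s, 0, -s * mu[1]), c(0, s, -s * mu[2]), c(0, 0, 1))
    list(p = cbind(s * (p[, 1] - mu[1]), s * (p[, 2] - mu[2])), T = Tm)
  }
  n1 <- normalize(p1); n2 <- normalize(p2)
  x <- n1$p[, 1]; y <- n1$p[, 2]; xp <- n2$p[, 1]; yp <- n2$p[, 2]
  n <- nrow(p1)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, xp * x, xp * y, xp)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, yp * x, yp * y, yp)
  sv <- svd(A, nu = 0, nv = 9)
  Hh <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(n2$T) %*% Hh %*% n1$T
  H / H[3, 3]
}

# least-squares affine transform (6 DOF) embedded as a homography
affineFit <- function(p1, p2) {
  if (nrow(p1) < 3) return(NULL)
  X <- cbind(p1, 1)
  cf <- tryCatch(qr.solve(X, p2), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  rbind(c(cf[1, 1], cf[2, 1], cf[3, 1]),
        c(cf[1, 2], cf[2, 2], cf[3, 2]),
        c(0, 0, 1))
}

applyHomographyPts <- function(H, p) {
  d <- H[3, 1] * p[, 1] + H[3, 2] * p[, 2] + H[3, 3]
  cbind((H[1, 1] * p[, 1] + H[1, 2] * p[, 2] + H[1, 3]) / d,
        (H[2, 1] * p[, 1] + H[2, 2] * p[, 2] + H[2, 3]) / d)
}

# robust homography fit: RANSAC with 3 px inlier threshold, refit on inliers
ransacHomography <- function(p1, p2, thresh = 3, iters = 2000, seed = 7L) {
  n <- nrow(p1)
  bestInl <- logical(n); bestCount <- 0L; bestH <- diag(3)
  withLocalSeed(seed, {
    for (it in seq_len(iters)) {
      s <- sample.int(n, 4)
      H <- tryCatch(dltHomography(p1[s, , drop = FALSE], p2[s, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H) || any(!is.finite(H))) next
      pr <- applyHomographyPts(H, p1)
      err <- sqrt(rowSums((pr - p2)^2))
      inl <- is.finite(err) & err < thresh
      if (sum(inl) > bestCount) {
        bestCount <- sum(inl); bestInl <- inl; bestH <- H
      }
    }
  })
  if (bestCount < 4) return(NULL)
  H <- bestH
  safeDlt <- function(keep, fallback) {
    tryCatch(dltHomography(p1[keep, , drop = FALSE],
                           p2[keep, , drop = FALSE]),
             error = function(e) fallback)
  }
  # iterated re-estimation with a tightening inlier threshold: the wide
  # first pass collects support, the narrow passes shed borderline false
  # matches that would bias the least-squares fit
  H <- safeDlt(bestInl, H)
  inl <- bestInl
  for (th in c(thresh, thresh / 2, thresh / 3)) {
    pr <- applyHomographyPts(H, p1)
    err <- sqrt(rowSums((pr - p2)^2))
    cand <- is.finite(err) & err < th
    if (sum(cand) < max(8, 4)) break
    inl <- cand
    H <- safeDlt(inl, H)
  }
  # guard against projective overfit: with noisy correspondences the two
  # perspective parameters amplify coordinate noise strongly. Select
  # between the affine and full projective model by split-half
  # cross-validation on the inliers, so the extra parameters must earn
  # their keep out of sample.
  q1 <- p1[inl, , drop = FALSE]; q2 <- p2[inl, , drop = FALSE]
  n1 <- nrow(q1)
  if (n1 >= 12) {
    a <- seq(1, n1, by = 2); b <- seq(2, n1, by = 2)
    cvErr <- function(fitFn) {
      e <- 0
      for (split in list(list(a, b), list(b, a))) {
        M <- fitFn(q1[split[[1]], , drop = FALSE],
                   q2[split[[1]], , drop = FALSE])
        if (is.null(M)) return(Inf)
        e <- e + mean(rowSums(
          (applyHomographyPts(M, q1[split[[2]], , drop = FALSE]) -
             q2[split[[2]], , drop = FALSE])^2))
      }
      e
    }
    safeFit <- function(f) function(x, y)
      tryCatch(f(x, y), error = function(e) NULL)
    if (cvErr(safeFit(affineFit)) <= cvErr(safeFit(dltHomography))) {
      Ha <- affineFit(q1, q2)
      if (!is.null(Ha)) H <- Ha
    }
  }
  pr <- applyHomographyPts(H, p1)
  err <- sqrt(rowSums((pr - p2)^2))
  inl2 <- is.finite(err) & err < thresh
  if (sum(inl2) >= 4) inl <- inl2
  list(H = H, inliers = inl, residual = mean(err[inl]))
}

#' Coarse (global) registration by keypoint matching
#'
#' Detects corner keypoints in both images, describes them with oriented
#' binary descriptors, matches by Hamming distance with a 0.75 ratio test,
#' and robustly fits a global homography (RANSAC, 3 px inlier threshold,
#' refit on inliers). The raw image is warped onto the reference frame.
#'
#' @param raw,reference numeric matrices of the same modality.
#' @param minInliers minimum geometrically consistent matches required; below
#'   this a registration-failure error (condition class
#'   `"registrationFailure"`, carrying `nMatches`) is signalled. The
#'   hard floor is 4 (a homography needs 4 correspondences); the stricter
#'   default rejects coincidental agreement between unrelated images.
#' @return an [AlignmentResult-class] with the estimated homography, the
#'   warped raw image, the inlier count and mean reprojection residual.
#' @export
coarseAlign <- function(raw, reference, minInliers = 8L) {
  if (!is.matrix(raw) || !is.matrix(reference))
    stop("raw and reference must be 2D matrices")
  k1 <- detectCorners(raw); k2 <- detectCorners(reference)
  if (nrow(k1) < 4 || nrow(k2) < 4)
    registrationFailure(
      sprintf("too few keypoints (%d raw, %d reference)", nrow(k1), nrow(k2)),
      nMatches = 0L)
  d1 <- briefDescriptors(raw, k1); d2 <- briefDescriptors(reference, k2)
  m <- matchDescriptors(d1, d2)
  if (nrow(m) < 4)
    registrationFailure(sprintf("only %d descriptor matches", nrow(m)),
                        nMatches = nrow(m))
  p1 <- cbind(k1[m[, 1], 2], k1[m[, 1], 1])  # (x, y)
  p2 <- cbind(k2[m[, 2], 2], k2[m[, 2], 1])
  fit <- ransacHomography(p1, p2)
  if (is.null(fit) || sum(fit$inliers) < max(4L, minInliers))
    registrationFailure(
      sprintf("only %d inlier matches (need >= %d)",
              if (is.null(fit)) 0L else sum(fit$inliers), max(4L, minInliers)),
      nMatches = if (is.null(fit)) 0L else sum(fit$inliers))
  # warp raw onto the reference frame: sample raw at H^{-1}(target)
  Hinv <- tryCatch(solve(fit$H), error = function(e)
    registrationFailure("estimated homography is degenerate",
                        nMatches = sum(fit$inliers)))
  warped <- warpHomography(raw, Hinv)
  new("AlignmentResult", homography = fit$H,
      flowField = array(0, c(0, 0, 0)), warped = warped,
      nMatches = as.integer(sum(fit$inliers)), residual = fit$residual)
}

# Farnebäck-style quadratic polynomial expansion: fits, per pixel, the local
# model f(x) ~ c + b'x + x'Ax under a Gaussian applicability. Returns the
# per-pixel A (2x2, symmetric) and b (2-vector) fields.
polyExpansion <- function(img, sigma = 1.5) {
  r <- max(2L, ceiling(3 * sigma))
  xk <- seq(-r, r)
  g <- exp(-xk^2 / (2 * sigma^2))
  gx <- g * xk
  gxx <- g * xk^2
  # separable Gaussian-weighted moments
  m00 <- sepConvolve(img, g, g)
  m10 <- sepConvolve(img, g, gx)    # weighted by x (cols)
  m01 <- sepConvolve(img, gx, g)    # weighted by y (rows)
  m20 <- sepConvolve(img, g, gxx)
  m02 <- sepConvolve(img, gxx, g)
  m11 <- sepConvolve(img, gx, gx)
  # metric G = sum a * b b' for basis (1, x, y, x^2, y^2, xy); separable sums
  s0 <- sum(g); s2 <- sum(gxx); s4 <- sum(g * xk^4)
  G <- matrix(0, 6, 6)
  G[1, 1] <- s0 * s0
  G[1, 4] <- G[4, 1] <- s2 * s0
  G[1, 5] <- G[5, 1] <- s0 * s2
  G[2, 2] <- s2 * s0
  G[3, 3] <- s0 * s2
  G[4, 4] <- s4 * s0
  G[5, 5] <- s0 * s4
  G[4, 5] <- G[5, 4] <- s2 * s2
  G[6, 6] <- s2 * s2
  Ginv <- solve(G)
  # coefficients: (c, cx, cy, cxx, cyy, cxy)
  cx  <- Ginv[2, 2] * m10
  cy  <- Ginv[3, 3] * m01
  cxx <- Ginv[4, 1] * m00 + Ginv[4, 4] * m20 + Ginv[4, 5] * m02
  cyy <- Ginv[5, 1] * m00 + Ginv[5, 4] * m20 + Ginv[5, 5] * m02
  cxy <- Ginv[6, 6] * m11
  list(bx = cx, by = cy, axx = cxx, ayy = cyy, axy = cxy / 2)
}

halfImage <- function(img) {
  h <- 2L * (nrow(img) %/% 2L); w <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(h), seq_len(w)]
  0.25 * (img[seq(1, h, 2), seq(1, w, 2)] + img[seq(2, h, 2), seq(1, w, 2)] +
          img[seq(1, h, 2), seq(2, w, 2)] + img[seq(2, h, 2), seq(2, w, 2)])
}

resizeBilinear <- function(img, newH, newW) {
  ys <- (seq_len(newH) - 0.5) * nrow(img) / newH + 0.5
  xs <- (seq_len(newW) - 0.5) * ncol(img) / newW + 0.5
  Y <- matrix(rep(ys, times = newW), newH, newW)
  X <- matrix(rep(xs, each = newH), newH, newW)
  bilinearSample(img, Y, X)
}

# dense displacement d with reference(x) ~ moving(x + d), single level
flowOneLevel <- function(reference, moving, flow, nIter = 3, aggSigma = 4) {
  h <- nrow(reference); w <- ncol(reference)
  p1 <- polyExpansion(reference)
  p2 <- polyExpansion(moving)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  rr <- matrix(rep(seq_len(h), times = w), h, w)
  for (it in seq_len(nIter)) {
    Yq <- rr + flow[, , 1]; Xq <- cc + flow[, , 2]
    axx <- 0.5 * (p1$axx + bilinearSample(p2$axx, Yq, Xq))
    ayy <- 0.5 * (p1$ayy + bilinearSample(p2$ayy, Yq, Xq))
    axy <- 0.5 * (p1$axy + bilinearSample(p2$axy, Yq, Xq))
    dbx <- -0.5 * (bilinearSample(p2$bx, Yq, Xq) - p1$bx) +
      axx * flow[, , 2] + axy * flow[, , 1]
    dby <- -0.5 * (bilinearSample(p2$by, Yq, Xq) - p1$by) +
      axy * flow[, , 2] + ayy * flow[, , 1]
    # Gaussian aggregation of the normal equations, then per-pixel 2x2 solve
    g11 <- gaussianBlur(axx * axx + axy * axy, aggSigma)
    g12 <- gaussianBlur(axx * axy + axy * ayy, aggSigma)
    g22 <- gaussianBlur(axy * axy + ayy * ayy, aggSigma)
    h1 <- gaussianBlur(axx * dbx + axy * dby, aggSigma)
    h2 <- gaussianBlur(axy * dbx + ayy * dby, aggSigma)
    det <- g11 * g22 - g12 * g12
    det[abs(det) < 1e-12] <- 1e-12
    dx <- (g22 * h1 - g12 * h2) / det
    dy <- (g11 * h2 - g12 * h1) / det
    flow[, , 1] <- dy
    flow[, , 2] <- dx
  }
  flow
}

#' Fine (local) registration by dense optical flow
#'
#' Estimates per-pixel displacements between a coarsely aligned image and
#' its reference with polynomial-expansion optical flow over a 3-level image
#' pyramid, then resamples the moving image through the field. Residual
#' drifts up to roughly 8 px are corrected.
#'
#' @param coarseWarped numeric matrix, output of the coarse stage.
#' @param reference numeric matrix of the same shape.
#' @param levels pyramid levels (default 3).
#' @param nIter displacement refinement iterations per level.
#' @return an [AlignmentResult-class] with the dense `flowField` (dy, dx),
#'   the resampled image, and residual = mean flow magnitude.
#' @export
fineAlign <- function(coarseWarped, reference, levels = 3L, nIter = 3L) {
  if (!all(dim(coarseWarped) == dim(reference)))
    stop("dimension mismatch between images")
  pyrRef <- list(reference); pyrMov <- list(coarseWarped)
  for (l in seq_len(levels - 1)) {
    if (min(dim(pyrRef[[l]])) < 32) { levels <- l; break }
    pyrRef[[l + 1]] <- halfImage(pyrRef[[l]])
    pyrMov[[l + 1]] <- halfImage(pyrMov[[l]])
  }
  flow <- array(0, c(dim(pyrRef[[levels]]), 2))
  for (l in seq(levels, 1)) {
    if (l < levels) {
      up <- array(0, c(dim(pyrRef[[l]]), 2))
      for (k in 1:2)
        up[, , k] <- 2 * resizeBilinear(flow[, , k],
                                        nrow(pyrRef[[l]]), ncol(pyrRef[[l]]))
      flow <- up
    }
    flow <- flowOneLevel(pyrRef[[l]], pyrMov[[l]], flow, nIter = nIter)
  }
  warped <- warpFlow(coarseWarped, flow)
  res <- mean(sqrt(flow[, , 1]^2 + flow[, , 2]^2))
  new("AlignmentResult", homography = diag(3), flowField = flow,
      warped = warped, nMatches = 0L, residual = res)
}

#' Tile an image into fixed-size patches
#'
#' Origins advance by `stride` from zero; when the last strided patch would
#' overrun, one final origin is snapped flush with the far edge so every
#' pixel is covered and all patches are full-size (edge-snap policy).
#'
#' @param image numeric matrix, at least `patchSize` in both axes.
#' @param patchSize patch side length (default 256).
#' @param stride stride between origins (default 196).
#' @return list with `grid` (a [PatchGrid-class]) and `patches` (list of
#'   `patchSize x patchSize` matrices, row-major order).
#' @export
cropPatches <- function(image, patchSize = 256L, stride = 196L) {
  h <- nrow(image); w <- ncol(image)
  patchSize <- as.integer(patchSize); stride <- as.integer(stride)
  if (h < patchSize || w < patchSize)
    stop("image (", h, " x ", w, ") smaller than patch size ", patchSize)
  grid <- makePatchGrid(c(h, w), patchSize, stride)
  list(grid = grid, patches = extractPatches(image, grid))
}

makePatchGrid <- function(shape, patchSize, stride) {
  axisOrigins <- function(n) {
    o <- seq(0L, n - patchSize, by = stride)
    if (o[length(o)] != n - patchSize) o <- c(o, n - patchSize)
    o
  }
  ro <- axisOrigins(shape[1]); co <- axisOrigins(shape[2])
  origins <- cbind(rep(ro, each = length(co)), rep(co, times = length(ro)))
  new("PatchGrid", patchSize = as.integer(patchSize),
      stride = as.integer(stride),
      origins = origins, sourceShape = as.integer(shape))
}

extractPatches <- function(image, grid) {
  ps <- grid@patchSize
  lapply(seq_len(nrow(grid@origins)), function(i) {
    o <- grid@origins[i, ]
    image[(o[1] + 1):(o[1] + ps), (o[2] + 1):(o[2] + ps)]
  })
}

#' Build an aligned patch-pair training dataset
#'
#' Runs coarse then fine alignment of each raw image onto its reference and
#' tiles both identically into patch pairs. Pairs whose coarse registration
#' fails are skipped and logged by index. When the estimated transforms are
#' negligible (corner displacement below 0.1 px, mean flow below 0.03 px)
#' the raw image is cropped without resampling, so undrifted inputs pass
#' through bit-exactly.
#'
#' @param rawList,referenceList lists of matrices, paired 1:1.
#' @param patchSize,stride tiling parameters (defaults 256 / 196).
#' @return list with `pairs` (list of `list(raw, reference)` patch pairs),
#'   `manifest` (data.frame: pair id, 9 homography values, residual,
#'   inlier count), and `skipped` (indices of unregistrable pairs).
#' @export
buildTrainingPairs <- function(rawList, referenceList,
                               patchSize = 256L, stride = 196L) {
  stopifnot(length(rawList) == length(referenceList))
  pairs <- list(); manifest <- NULL; skipped <- integer(0)
  for (i in seq_along(rawList)) {
    raw <- rawList[[i]]; ref <- referenceList[[i]]
    ca <- tryCatch(coarseAlign(raw, ref), registrationFailure = function(e) e)
    if (inherits(ca, "registrationFailure")) {
      skipped <- c(skipped, i)
      next
    }
    corners <- cbind(c(1, 1, ncol(ref), ncol(ref)),
                     c(1, nrow(ref), 1, nrow(ref)))
    shift <- max(sqrt(rowSums(
      (applyHomographyPts(ca@homography, corners) - corners)^2)))
    coarse <- if (shift < 0.1) raw else ca@warped
    fa <- fineAlign(coarse, ref)
    # compose both stages into a single resampling of the raw image
    aligned <- if (shift < 0.1 && fa@residual < 0.03) raw
    else if (fa@residual < 0.03) ca@warped
    else warpHomography(raw, solve(ca@homography), flow = fa@flowField)
    cr <- cropPatches(aligned, patchSize, stride)
    cf <- cropPatches(ref, patchSize, stride)
    pairs <- c(pairs, lapply(seq_along(cr$patches), function(k)
      list(raw = cr$patches[[k]], reference = cf$patches[[k]])))
    manifest <- rbind(manifest, data.frame(
      pair = i, t(as.vector(t(ca@homography))),
      residual = ca@residual, nMatches = ca@nMatches))
  }
  if (!is.null(manifest))
    names(manifest) <- c("pair", paste0("h", 1:9), "residual", "nMatches")
  list(pairs = pairs, manifest = manifest, skipped = skipped)
}
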