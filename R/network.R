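# Convolutional network substrate for the diffusion engine. Activations are
# stored flat as (npix x channels) matrices in column-major pixel order;
# 3x3 convolutions (zero padded) are im2col matrix products built from
# memoized gather indices, so the hot path is pure BLAS.

.idxCache <- new.env(parent = emptyenv())

# gather indices: for each of the 9 kernel offsets, the rows of the padded
# (h+2)(w+2) pixel matrix contributing to each output pixel
convIdx <- function(h, w) {
  key <- paste0("c", h, "x", w)
  got <- .idxCache[[key]]
  if (!is.null(got)) return(got)
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  idx <- vector("list", 9L)
  k <- 0L
  for (kx in 0:2) for (ky in 0:2) {
    k <- k + 1L
    idx[[k]] <- (rr + ky) + (cc + kx - 1L) * (h + 2L)
  }
  # padded interior rows (to scatter/gather the unpadded image)
  interior <- (rr + 1L) + cc * (h + 2L)
  out <- list(idx = idx, interior = interior, h = h, w = w)
  .idxCache[[key]] <- out
  out
}

poolIdx <- function(h, w) {
  key <- paste0("p", h, "x", w)
  got <- .idxCache[[key]]
  if (!is.null(got)) return(got)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  rr <- rep(seq_len(h2), times = w2)
  cc <- rep(seq_len(w2), each = h2)
  at <- function(dr, dc) (2L * rr - 1L + dr) + (2L * cc - 2L + dc) * h
  out <- list(i00 = at(0L, 0L), i10 = at(1L, 0L),
              i01 = at(0L, 1L), i11 = at(1L, 1L), h2 = h2, w2 = w2)
  .idxCache[[key]] <- out
  out
}

padFlat <- function(X, h, w) {
  ci <- convIdx(h, w)
  Xp <- matrix(0, (h + 2L) * (w + 2L), ncol(X))
  Xp[ci$interior, ] <- X
  Xp
}

im2colFlat <- function(X, h, w) {
  ci <- convIdx(h, w)
  cin <- ncol(X)
  Xp <- padFlat(X, h, w)
  P <- matrix(0, h * w, 9L * cin)
  for (k in 1:9)
    P[, (k - 1L) * cin + seq_len(cin)] <- Xp[ci$idx[[k]], , drop = FALSE]
  P
}

convFwd <- function(X, h, w, W, b) {
  P <- im2colFlat(X, h, w)
  Y <- P %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(y = Y, P = P, cin = ncol(X))
}

# input gradient of a zero-padded 3x3 conv is the conv of dY with the
# spatially flipped, channel-transposed kernel — gather + BLAS, no scatter
flipKernel <- function(W, cin) {
  cout <- ncol(W)
  Warr <- array(W, c(cin, 9L, cout))
  matrix(aperm(Warr[, 9:1, , drop = FALSE], c(3, 2, 1)), 9L * cout, cin)
}

convBwd <- function(dY, cache, W, h, w) {
  list(dW = crossprod(cache$P, dY), db = colSums(dY),
       dx = im2colFlat(dY, h, w) %*% flipKernel(W, cache$cin))
}

conv1Fwd <- function(X, W, b) {
  Y <- X %*% W
  list(y = Y + rep(b, each = nrow(Y)), X = X)
}

conv1Bwd <- function(dY, cache, W) {
  list(dW = crossprod(cache$X, dY), db = colSums(dY), dx = dY %*% t(W))
}

siluFwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, s = s, x = x)
}

siluBwd <- function(dY, cache) {
  dY * (cache$s * (1 + cache$x * (1 - cache$s)))
}

poolFwd <- function(X, h, w) {
  pi <- poolIdx(h, w)
  0.25 * (X[pi$i00, , drop = FALSE] + X[pi$i10, , drop = FALSE] +
          X[pi$i01, , drop = FALSE] + X[pi$i11, , drop = FALSE])
}

poolBwd <- function(dY, h, w) {
  pi <- poolIdx(h, w)
  out <- matrix(0, h * w, ncol(dY))
  q <- 0.25 * dY
  out[pi$i00, ] <- q; out[pi$i10, ] <- q
  out[pi$i01, ] <- out[pi$i01, , drop = FALSE] + q
  out[pi$i11, ] <- out[pi$i11, , drop = FALSE] + q
  out
}

upFwd <- function(X, h2, w2) {   # nearest neighbour x2; output (2h2 x 2w2)
  pi <- poolIdx(2L * h2, 2L * w2)
  out <- matrix(0, 4L * h2 * w2, ncol(X))
  out[pi$i00, ] <- X; out[pi$i10, ] <- X
  out[pi$i01, ] <- X; out[pi$i11, ] <- X
  out
}

upBwd <- function(dY, h2, w2) {
  pi <- poolIdx(2L * h2, 2L * w2)
  dY[pi$i00, , drop = FALSE] + dY[pi$i10, , drop = FALSE] +
    dY[pi$i01, , drop = FALSE] + dY[pi$i11, , drop = FALSE]
}

#' Sinusoidal positional encoding of an integer layer index
#'
#' Embeds the target-layer index `j` (its relative position between the
#' upper and lower condition layers) as the standard sinusoidal positional
#' encoding, so one network can generate any of the R intermediate layers
#' without architectural change. The same encoding is used internally for
#' the diffusion timestep.
#'
#' @param j integer index in `[1, R]`.
#' @param R number of interpolation layers.
#' @param dim embedding dimension (even).
#' @return numeric vector of length `dim`.
#' @export
channelEmbed <- function(j, R, dim = 32L) {
  if (dim %% 2 != 0) stop("embedding dim must be even")
  if (length(j) != 1 || j < 1 || j > R)
    stop("j must lie in [1, R] (got j = ", j, ", R = ", R, ")")
  sinusoidalEmbed(j, dim)
}

sinusoidalEmbed <- function(v, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / half)
  c(sin(v * freqs), cos(v * freqs))
}

#' Construct the two-head conditional diffusion network
#'
#' A U-shaped encoder–bottleneck–decoder with skip connections operating on
#' the channel concatenation of the noisy state `x_t` and the condition
#' stack, modulated by a sinusoidal timestep embedding (plus a layer-index
#' channel embedding for volumetric interpolation). Two 1x1 heads produce
#' the noise prediction and the per-pixel difficulty map: the difficulty
#' head outputs log(phi), clamped to \[-10, 10\] before exponentiation, so
#' phi is positive by construction. Parameters are partitioned into named
#' groups (encoder, bottleneck, decoder, heads) so fine-tuning can freeze
#' the encoder.
#'
#' The noise head is parameterised through the clean image: the network
#' predicts a correction to an analytic base restoration (the condition
#' itself for denoising/super-resolution; the j-weighted linear blend of
#' the two condition layers for volumetric interpolation), and the noise
#' prediction is derived from it in closed form at the current timestep.
#' At initialisation the sampler therefore reproduces the base
#' restoration, and training spends its budget entirely on the correction.
#'
#' @param condChannels number of condition images (1 for denoising and
#'   super-resolution, 2 for volumetric interpolation).
#' @param baseWidth channel width of the first stage.
#' @param embDim timestep/channel embedding dimension.
#' @param useChannelEmbed whether a layer index j is expected at every call.
#' @param R interpolation count of the volumes the network will be trained
#'   on (needed with `useChannelEmbed` to form the j-weighted base blend).
#' @param seed weight initialisation seed.
#' @return an object of class `DiffusionNet` (list of parameters, group
#'   manifest and configuration).
#' @export
makeNetwork <- function(condChannels = 1L, baseWidth = 16L, embDim = 32L,
                        useChannelEmbed = FALSE, R = NULL, seed = 1L) {
  if (condChannels < 1 || baseWidth < 2 || embDim < 2 || embDim %% 2 != 0)
    stop("invalid network configuration")
  w <- as.integer(baseWidth)
  cin <- 1L + as.integer(condChannels)
  he <- function(nin, nout, k = 9L) {
    matrix(stats::rnorm(k * nin * nout, sd = sqrt(2 / (k * nin))),
           k * nin, nout)
  }
  params <- withLocalSeed(seed, list(
    enc1a.W = he(cin, w), enc1a.b = numeric(w),
    enc1b.W = he(w, w),   enc1b.b = numeric(w),
    t1.W = matrix(stats::rnorm(2L * embDim * w, sd = 0.02), 2L * embDim, w),
    enc2a.W = he(w, 2 * w), enc2a.b = numeric(2 * w),
    enc2b.W = he(2 * w, 2 * w), enc2b.b = numeric(2 * w),
    t2.W = matrix(stats::rnorm(2L * embDim * 2 * w, sd = 0.02),
                  2L * embDim, 2 * w),
    bota.W = he(2 * w, 2 * w), bota.b = numeric(2 * w),
    botb.W = he(2 * w, 2 * w), botb.b = numeric(2 * w),
    t3.W = matrix(stats::rnorm(2L * embDim * 2 * w, sd = 0.02),
                  2L * embDim, 2 * w),
    dec2a.W = he(4 * w, 2 * w), dec2a.b = numeric(2 * w),
    dec2b.W = he(2 * w, w), dec2b.b = numeric(w),
    t4.W = matrix(stats::rnorm(2L * embDim * w, sd = 0.02), 2L * embDim, w),
    dec1a.W = he(2 * w, w), dec1a.b = numeric(w),
    dec1b.W = he(w, w), dec1b.b = numeric(w),
    t5.W = matrix(stats::rnorm(2L * embDim * w, sd = 0.02), 2L * embDim, w),
    headE.W = matrix(0, w, 1L), headE.b = numeric(1),
    headP.W = matrix(0, w, 1L), headP.b = numeric(1)
  ))
  groups <- c(
    enc1a.W = "encoder", enc1a.b = "encoder", enc1b.W = "encoder",
    enc1b.b = "encoder", t1.W = "encoder", enc2a.W = "encoder",
    enc2a.b = "encoder", enc2b.W = "encoder", enc2b.b = "encoder",
    t2.W = "encoder",
    bota.W = "bottleneck", bota.b = "bottleneck", botb.W = "bottleneck",
    botb.b = "bottleneck", t3.W = "bottleneck",
    dec2a.W = "decoder", dec2a.b = "decoder", dec2b.W = "decoder",
    dec2b.b = "decoder", t4.W = "decoder", dec1a.W = "decoder",
    dec1a.b = "decoder", dec1b.W = "decoder", dec1b.b = "decoder",
    t5.W = "decoder",
    headE.W = "heads", headE.b = "heads", headP.W = "heads", headP.b = "heads"
  )
  structure(list(
    params = params, groups = groups,
    config = list(condChannels = as.integer(condChannels), baseWidth = w,
                  embDim = as.integer(embDim),
                  useChannelEmbed = isTRUE(useChannelEmbed),
                  R = if (is.null(R)) NULL else as.integer(R), seed = seed),
    opt = NULL
  ), class = "DiffusionNet")
}

#' @export
print.DiffusionNet <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "DiffusionNet: %d parameters, base width %d, %d condition channel(s)%s\n",
    np, x$config$baseWidth, x$config$condChannels,
    if (x$config$useChannelEmbed) ", with channel embedding" else ""))
  invisible(x)
}

#' Parameter groups of a network
#'
#' @param net a `DiffusionNet`.
#' @return named list mapping group name (encoder, bottleneck, decoder,
#'   heads) to the parameter names it contains; the groups are disjoint
#'   and exhaustive.
#' @export
parameterGroups <- function(net) {
  split(names(net$groups), unname(net$groups))
}

combinedEmbedding <- function(net, t, j) {
  ed <- net$config$embDim
  te <- sinusoidalEmbed(t, ed)
  je <- if (net$config$useChannelEmbed) {
    if (is.null(j)) stop("this network requires a layer index j")
    sinusoidalEmbed(j, ed)
  } else numeric(ed)
  c(te, je)
}

# analytic base restoration the correction head is anchored to
baseRestoration <- function(net, X, j) {
  cc <- net$config$condChannels
  if (cc == 1L) return(X[, 2])
  if (cc == 2L) {
    R <- net$config$R
    if (!is.null(R) && !is.null(j)) {
      wj <- j / (R + 1)
      return((1 - wj) * X[, 2] + wj * X[, 3])
    }
    return(0.5 * (X[, 2] + X[, 3]))
  }
  rowMeans(X[, -1, drop = FALSE])
}

# forward pass; inputs xt (matrix) and cond (matrix or H x W x C array) in
# model range [-1, 1]; spatial dims padded to a multiple of 4 internally.
# When `abar` (the schedule's cumulative retention at t) is supplied, the
# noise head is derived from the predicted clean image x0hat = clamp(base +
# correction); without it the raw correction head is returned as epsHat.
netForward <- function(net, xt, cond, t, j = NULL, abar = NULL,
                       keepCache = FALSE) {
  if (is.matrix(cond)) cond <- array(cond, c(dim(cond), 1L))
  if (dim(cond)[3] != net$config$condChannels)
    stop("condition stack has ", dim(cond)[3], " channels; network expects ",
         net$config$condChannels)
  if (!all(dim(xt) == dim(cond)[1:2]))
    stop("x_t and condition are not spatially congruent")
  h0 <- nrow(xt); w0 <- ncol(xt)
  ph <- (4 - h0 %% 4) %% 4; pw <- (4 - w0 %% 4) %% 4
  H <- h0 + ph; W <- w0 + pw
  if (ph > 0 || pw > 0) {
    padM <- function(m) {
      m <- rbind(m, m[reflectIndex(h0 + seq_len(ph), h0), , drop = FALSE])
      cbind(m, m[, reflectIndex(w0 + seq_len(pw), w0), drop = FALSE])
    }
    xt <- padM(xt)
    cond2 <- array(0, c(H, W, dim(cond)[3]))
    for (c in seq_len(dim(cond)[3])) cond2[, , c] <- padM(cond[, , c])
    cond <- cond2
  }
  p <- net$params
  emb <- combinedEmbedding(net, t, j)
  tb <- function(Wt) as.numeric(emb %*% Wt)
  np <- H * W
  X <- cbind(as.numeric(xt), matrix(cond, np, dim(cond)[3]))
  h2 <- H %/% 2L; w2 <- W %/% 2L
  h4 <- H %/% 4L; w4 <- W %/% 4L

  c1a <- convFwd(X, H, W, p$enc1a.W, p$enc1a.b); a1a <- siluFwd(c1a$y)
  c1b <- convFwd(a1a$y, H, W, p$enc1b.W, p$enc1b.b)
  a1b <- siluFwd(c1b$y + rep(tb(p$t1.W), each = np))
  d1 <- poolFwd(a1b$y, H, W)
  c2a <- convFwd(d1, h2, w2, p$enc2a.W, p$enc2a.b); a2a <- siluFwd(c2a$y)
  c2b <- convFwd(a2a$y, h2, w2, p$enc2b.W, p$enc2b.b)
  a2b <- siluFwd(c2b$y + rep(tb(p$t2.W), each = h2 * w2))
  d2 <- poolFwd(a2b$y, h2, w2)
  cba <- convFwd(d2, h4, w4, p$bota.W, p$bota.b); aba <- siluFwd(cba$y)
  cbb <- convFwd(aba$y, h4, w4, p$botb.W, p$botb.b)
  abb <- siluFwd(cbb$y + rep(tb(p$t3.W), each = h4 * w4))
  u2 <- upFwd(abb$y, h4, w4)
  s2 <- cbind(u2, a2b$y)
  cd2a <- convFwd(s2, h2, w2, p$dec2a.W, p$dec2a.b); ad2a <- siluFwd(cd2a$y)
  cd2b <- convFwd(ad2a$y, h2, w2, p$dec2b.W, p$dec2b.b)
  ad2b <- siluFwd(cd2b$y + rep(tb(p$t4.W), each = h2 * w2))
  u1 <- upFwd(ad2b$y, h2, w2)
  s1 <- cbind(u1, a1b$y)
  cd1a <- convFwd(s1, H, W, p$dec1a.W, p$dec1a.b); ad1a <- siluFwd(cd1a$y)
  cd1b <- convFwd(ad1a$y, H, W, p$dec1b.W, p$dec1b.b)
  ad1b <- siluFwd(cd1b$y + rep(tb(p$t5.W), each = np))
  hE <- conv1Fwd(ad1b$y, p$headE.W, p$headE.b)
  hP <- conv1Fwd(ad1b$y, p$headP.W, p$headP.b)
  logphiRaw <- hP$y[, 1]
  logphi <- clamp(logphiRaw, -10, 10)
  u <- hE$y[, 1]
  if (is.null(abar)) {
    epsFlat <- u
    x0ClampMask <- NULL
    epsScale <- 1
  } else {
    b <- baseRestoration(net, X, j)
    x0raw <- b + u
    x0ClampMask <- x0raw > -1 & x0raw < 1
    x0hat <- clamp(x0raw, -1, 1)
    epsScale <- -sqrt(abar) / sqrt(1 - abar)
    epsFlat <- (X[, 1] - sqrt(abar) * x0hat) / sqrt(1 - abar)
  }
  epsM <- matrix(epsFlat, H, W)
  phiM <- matrix(exp(logphi), H, W)
  out <- list(epsHat = epsM[seq_len(h0), seq_len(w0)],
              phi = phiM[seq_len(h0), seq_len(w0)])
  if (keepCache) {
    out$cache <- list(
      emb = emb, pad = c(h0, w0, ph, pw),
      c1a = c1a, a1a = a1a, c1b = c1b, a1b = a1b,
      c2a = c2a, a2a = a2a, c2b = c2b, a2b = a2b,
      cba = cba, aba = aba, cbb = cbb, abb = abb,
      cd2a = cd2a, ad2a = ad2a, cd2b = cd2b, ad2b = ad2b,
      cd1a = cd1a, ad1a = ad1a, cd1b = cd1b, ad1b = ad1b,
      hE = hE, hP = hP, logphiRaw = logphiRaw,
      epsScale = epsScale, x0ClampMask = x0ClampMask
    )
  }
  out
}

# backward pass; dEps and dLogphi are gradients at the original (cropped)
# size; returns the parameter gradient list
netBackward <- function(net, cache, dEps, dLogphi) {
  p <- net$params
  h0 <- cache$pad[1]; w0 <- cache$pad[2]
  ph <- cache$pad[3]; pw <- cache$pad[4]
  H <- h0 + ph; W <- w0 + pw
  np <- H * W
  h2 <- H %/% 2L; w2 <- W %/% 2L
  h4 <- H %/% 4L; w4 <- W %/% 4L
  dEm <- matrix(0, H, W); dEm[seq_len(h0), seq_len(w0)] <- dEps
  dPm <- matrix(0, H, W); dPm[seq_len(h0), seq_len(w0)] <- dLogphi
  dE <- matrix(as.numeric(dEm) * cache$epsScale, np, 1L)
  if (!is.null(cache$x0ClampMask)) dE <- dE * cache$x0ClampMask
  mask <- cache$logphiRaw > -10 & cache$logphiRaw < 10
  dP <- matrix(as.numeric(dPm) * mask, np, 1L)
  g <- list()
  emb <- cache$emb
  tgrad <- function(dy) tcrossprod(emb, colSums(dy))
  gE <- conv1Bwd(dE, cache$hE, p$headE.W)
  gP <- conv1Bwd(dP, cache$hP, p$headP.W)
  g$headE.W <- gE$dW; g$headE.b <- gE$db
  g$headP.W <- gP$dW; g$headP.b <- gP$db
  dy <- siluBwd(gE$dx + gP$dx, cache$ad1b)
  g$t5.W <- tgrad(dy)
  gc1 <- convBwd(dy, cache$cd1b, p$dec1b.W, H, W)
  g$dec1b.W <- gc1$dW; g$dec1b.b <- gc1$db
  dy <- siluBwd(gc1$dx, cache$ad1a)
  gc2 <- convBwd(dy, cache$cd1a, p$dec1a.W, H, W)
  g$dec1a.W <- gc2$dW; g$dec1a.b <- gc2$db
  wch <- net$config$baseWidth
  du1 <- gc2$dx[, seq_len(wch), drop = FALSE]
  da1bSkip <- gc2$dx[, wch + seq_len(wch), drop = FALSE]
  dy <- siluBwd(upBwd(du1, h2, w2), cache$ad2b)
  g$t4.W <- tgrad(dy)
  gc3 <- convBwd(dy, cache$cd2b, p$dec2b.W, h2, w2)
  g$dec2b.W <- gc3$dW; g$dec2b.b <- gc3$db
  dy <- siluBwd(gc3$dx, cache$ad2a)
  gc4 <- convBwd(dy, cache$cd2a, p$dec2a.W, h2, w2)
  g$dec2a.W <- gc4$dW; g$dec2a.b <- gc4$db
  du2 <- gc4$dx[, seq_len(2 * wch), drop = FALSE]
  da2bSkip <- gc4$dx[, 2 * wch + seq_len(2 * wch), drop = FALSE]
  dy <- siluBwd(upBwd(du2, h4, w4), cache$abb)
  g$t3.W <- tgrad(dy)
  gc5 <- convBwd(dy, cache$cbb, p$botb.W, h4, w4)
  g$botb.W <- gc5$dW; g$botb.b <- gc5$db
  dy <- siluBwd(gc5$dx, cache$aba)
  gc6 <- convBwd(dy, cache$cba, p$bota.W, h4, w4)
  g$bota.W <- gc6$dW; g$bota.b <- gc6$db
  dy <- siluBwd(poolBwd(gc6$dx, h2, w2) + da2bSkip, cache$a2b)
  g$t2.W <- tgrad(dy)
  gc7 <- convBwd(dy, cache$c2b, p$enc2b.W, h2, w2)
  g$enc2b.W <- gc7$dW; g$enc2b.b <- gc7$db
  dy <- siluBwd(gc7$dx, cache$a2a)
  gc8 <- convBwd(dy, cache$c2a, p$enc2a.W, h2, w2)
  g$enc2a.W <- gc8$dW; g$enc2a.b <- gc8$db
  dy <- siluBwd(poolBwd(gc8$dx, H, W) + da1bSkip, cache$a1b)
  g$t1.W <- tgrad(dy)
  gc9 <- convBwd(dy, cache$c1b, p$enc1b.W, H, W)
  g$enc1b.W <- gc9$dW; g$enc1b.b <- gc9$db
  dy <- siluBwd(gc9$dx, cache$a1a)
  gc10 <- convBwd(dy, cache$c1a, p$enc1a.W, H, W)
  g$enc1a.W <- gc10$dW; g$enc1a.b <- gc10$db
  g
}

initAdam <- function(net) {
  net$opt <- list(
    m = lapply(net$params, function(p) p * 0),
    v = lapply(net$params, function(p) p * 0),
    t = 0L
  )
  net
}

adamStep <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, freeze = character(0),
                     lrScale = NULL) {
  if (is.null(net$opt)) net <- initAdam(net)
  net$opt$t <- net$opt$t + 1L
  tt <- net$opt$t
  for (nm in names(net$params)) {
    if (net$groups[[nm]] %in% freeze) next
    gr <- grads[[nm]]
    if (is.null(gr)) next
    lrp <- lr
    if (!is.null(lrScale) && nm %in% names(lrScale))
      lrp <- lr * lrScale[[nm]]
    net$opt$m[[nm]] <- beta1 * net$opt$m[[nm]] + (1 - beta1) * gr
    net$opt$v[[nm]] <- beta2 * net$opt$v[[nm]] + (1 - beta2) * gr^2
    mh <- net$opt$m[[nm]] / (1 - beta1^tt)
    vh <- net$opt$v[[nm]] / (1 - beta2^tt)
    net$params[[nm]] <- net$params[[nm]] - lrp * mh / (sqrt(vh) + eps)
  }
  net
}
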