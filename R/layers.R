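# CNN building blocks implemented from first principles on BLAS matrix
# products. Feature maps are numeric arrays indexed (row, col, channel,
# sample); plain matrices are promoted to single-channel single-sample
# stacks. Convolution is cross-correlation (no kernel flip), the modern
# CNN convention.

# Promote (H,W) or (H,W,C) to (H,W,C,N).
asFeatureMap <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps must be matrices or arrays",
                       call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L)
    stop("feature maps must have 2-4 dimensions", call. = FALSE)
  x
}

asKernel4 <- function(k) {
  d <- dim(k)
  if (is.null(d)) stop("kernels must be matrices or 4D arrays",
                       call. = FALSE)
  if (length(d) == 2L) dim(k) <- c(d, 1L, 1L)
  else if (length(d) != 4L)
    stop("kernels must be (kh, kw, inC, outC) arrays", call. = FALSE)
  k
}

# Drop singleton channel/sample dims so callers that passed a matrix get a
# matrix back.
dropLike <- function(out, original) {
  nd <- length(dim(original))
  if (is.null(dim(original)) || nd == 4L) return(out)
  d <- dim(out)
  if (nd == 2L && d[3] == 1L && d[4] == 1L) dim(out) <- d[1:2]
  else if (nd == 3L && d[4] == 1L) dim(out) <- d[1:3]
  out
}

# im2col: unfold kh x kw patches of a padded feature-map stack into a
# (kh*kw*C) x (Ho*Wo*N) matrix whose row order matches the column-major
# flattening of a (kh, kw, C, outC) kernel array.
im2col <- function(x, kh, kw, padH, padW, stride = 1L) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (padH > 0L || padW > 0L) {
    xp <- array(0, c(H + 2L * padH, W + 2L * padW, C, N))
    xp[padH + seq_len(H), padW + seq_len(W), , ] <- x
  } else xp <- x
  Ho <- (H + 2L * padH - kh) %/% stride + 1L
  Wo <- (W + 2L * padW - kw) %/% stride + 1L
  if (Ho < 1L || Wo < 1L)
    stop("kernel larger than (padded) input", call. = FALSE)
  posR <- seq.int(1L, by = stride, length.out = Ho)
  posC <- seq.int(1L, by = stride, length.out = Wo)
  P <- array(0, c(kh, kw, C, Ho, Wo, N))
  for (dh in seq_len(kh)) for (dw in seq_len(kw)) {
    sl <- xp[posR + dh - 1L, posC + dw - 1L, , , drop = FALSE]
    P[dh, dw, , , , ] <- aperm(sl, c(3L, 1L, 2L, 4L))
  }
  dim(P) <- c(kh * kw * C, Ho * Wo * N)
  list(P = P, Ho = Ho, Wo = Wo, padH = padH, padW = padW,
       posR = posR, posC = posC, inDim = d)
}

# Scatter-add the patch-gradient matrix back onto the input grid (the
# adjoint of im2col).
col2im <- function(dP, kh, kw, cache) {
  d <- cache$inDim
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  padH <- cache$padH; padW <- cache$padW
  Ho <- cache$Ho; Wo <- cache$Wo
  dim(dP) <- c(kh, kw, C, Ho, Wo, N)
  dxp <- array(0, c(H + 2L * padH, W + 2L * padW, C, N))
  for (dh in seq_len(kh)) for (dw in seq_len(kw)) {
    sl <- dP[dh, dw, , , , , drop = FALSE]
    dim(sl) <- c(C, Ho, Wo, N)
    dxp[cache$posR + dh - 1L, cache$posC + dw - 1L, , ] <-
      dxp[cache$posR + dh - 1L, cache$posC + dw - 1L, , , drop = FALSE] +
      aperm(sl, c(2L, 3L, 1L, 4L))
  }
  dxp[padH + seq_len(H), padW + seq_len(W), , , drop = FALSE]
}

samePad <- function(k) {
  if (k %% 2L == 0L)
    stop("'same' padding requires odd kernel sizes", call. = FALSE)
  (k - 1L) %/% 2L
}

#' Convolutional layer forward pass
#'
#' Each output channel is the sum over input channels of the
#' cross-correlation of the input map with the matching kernel slab, plus a
#' per-output-channel bias. With `padding = "same"` (stride 1, odd kernels)
#' the spatial dimensions are preserved; with `"valid"` the output shrinks
#' by the kernel extent and `stride` subsamples the output grid.
#'
#' @param input feature maps: matrix `(H, W)` or array `(H, W, C, N)`.
#' @param kernels array `(kh, kw, inC, outC)` (a matrix is taken as a
#'   single-channel kernel).
#' @param bias numeric of length `outC`, or NULL for zero bias.
#' @param stride positive integer output stride (valid padding only).
#' @param padding `"same"` or `"valid"`.
#' @return Feature maps with `outC` channels, shaped like the input
#'   convention that was passed in.
#' @examples
#' convForward(matrix(c(1, 3, 2, 4), 2), matrix(1, 2, 2), padding = "valid")
#' @export
convForward <- function(input, kernels, bias = NULL, stride = 1L,
                        padding = c("same", "valid")) {
  padding <- match.arg(padding)
  x <- asFeatureMap(input)
  k <- asKernel4(kernels)
  kd <- dim(k)
  if (dim(x)[3] != kd[3])
    stop(sprintf("input has %d channels but kernels expect %d",
                 dim(x)[3], kd[3]), call. = FALSE)
  if (padding == "same" && stride != 1L)
    stop("'same' padding requires stride 1", call. = FALSE)
  pad <- if (padding == "same") c(samePad(kd[1]), samePad(kd[2]))
         else c(0L, 0L)
  ic <- im2col(x, kd[1], kd[2], pad[1], pad[2], as.integer(stride))
  Km <- k; dim(Km) <- c(kd[1] * kd[2] * kd[3], kd[4])
  Y <- crossprod(Km, ic$P)
  if (!is.null(bias)) {
    if (length(bias) != kd[4])
      stop("bias length must equal the output channel count", call. = FALSE)
    Y <- Y + bias
  }
  dim(Y) <- c(kd[4], ic$Ho, ic$Wo, dim(x)[4])
  dropLike(aperm(Y, c(2L, 3L, 1L, 4L)), input)
}

# Backward pass for convForward given the cached im2col matrix.
convBackward <- function(dOut, kernels, cache) {
  k <- asKernel4(kernels)
  kd <- dim(k)
  dY <- aperm(asFeatureMap(dOut), c(3L, 1L, 2L, 4L))
  nPix <- cache$Ho * cache$Wo * cache$inDim[4]
  dim(dY) <- c(kd[4], nPix)
  Km <- k; dim(Km) <- c(kd[1] * kd[2] * kd[3], kd[4])
  dK <- cache$P %*% t(dY)
  dim(dK) <- kd
  dP <- Km %*% dY
  list(dInput = col2im(dP, kd[1], kd[2], cache),
       dKernels = dK, dBias = rowSums(dY))
}

#' Rectified linear activation and its derivative
#'
#' `relu(x) = max(0, x)` elementwise; `reluGrad` is its derivative, 1 for
#' positive inputs and 0 otherwise (the subgradient 0 is used at x = 0).
#'
#' @param x numeric vector, matrix or array.
#' @return An object shaped like `x`.
#' @examples
#' relu(c(-3, 0, 5))
#' reluGrad(c(-1, 0, 2))
#' @export
relu <- function(x) x * (x > 0)

#' @rdname relu
#' @export
reluGrad <- function(x) (x > 0) * 1

#' Batch normalization
#'
#' Standardizes each channel by its batch mean and (population) variance,
#' stabilized by `epsilon` in the denominator, then applies the learnable
#' affine transform `scale * xhat + shift`. In training mode the batch
#' statistics are taken over all samples and spatial positions of each
#' channel and the running statistics are updated by an exponential moving
#' average; in inference mode the stored running statistics are used, so
#' repeated inference is deterministic.
#'
#' @param input feature maps `(H, W, C, N)` (matrix promoted).
#' @param scale,shift per-channel affine parameters (default 1 and 0).
#' @param epsilon positive stability constant.
#' @param training logical; batch statistics vs running statistics.
#' @param runningMean,runningVar per-channel running statistics (required
#'   in inference mode).
#' @param momentum EMA weight for the running-statistics update.
#' @return A list: `output` (shaped like the input), `normalized` (the
#'   pre-affine standardized maps), `batchMean`, `batchVar`,
#'   `runningMean`, `runningVar`.
#' @examples
#' b <- array(c(1, 2, 3), c(1, 1, 1, 3))
#' batchNorm(b, epsilon = 1e-12)$output
#' @export
batchNorm <- function(input, scale = NULL, shift = NULL, epsilon = 1e-5,
                      training = TRUE, runningMean = NULL,
                      runningVar = NULL, momentum = 0.1) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  x <- asFeatureMap(input)
  d <- dim(x)
  C <- d[3]; perChan <- d[1] * d[2]
  if (is.null(scale)) scale <- rep(1, C)
  if (is.null(shift)) shift <- rep(0, C)
  if (training) {
    if (d[4] < 2L)
      stop("training-mode batch normalization needs >= 2 samples",
           call. = FALSE)
    xc <- aperm(x, c(1L, 2L, 4L, 3L))
    dim(xc) <- c(perChan * d[4], C)
    mu <- colMeans(xc)
    v <- colMeans(xc * xc) - mu^2
    v <- pmax(v, 0)
    runningMean <- if (is.null(runningMean)) mu
                   else (1 - momentum) * runningMean + momentum * mu
    runningVar <- if (is.null(runningVar)) v
                  else (1 - momentum) * runningVar + momentum * v
  } else {
    if (is.null(runningMean) || is.null(runningVar))
      stop("inference-mode batch normalization needs running statistics",
           call. = FALSE)
    mu <- runningMean
    v <- runningVar
  }
  muRep <- rep(mu, each = perChan)
  sdRep <- rep(sqrt(v + epsilon), each = perChan)
  xhat <- (x - as.vector(muRep)) / as.vector(sdRep)  # recycles over samples
  out <- xhat * as.vector(rep(scale, each = perChan)) +
    as.vector(rep(shift, each = perChan))
  list(output = dropLike(out, input),
       normalized = dropLike(xhat, input),
       batchMean = mu, batchVar = v,
       runningMean = runningMean, runningVar = runningVar)
}

# Gradient of batchNorm (training mode) w.r.t. input, scale and shift.
batchNormBackward <- function(dOut, xhat, scale, batchVar, epsilon) {
  d <- dim(dOut)
  C <- d[3]; perChan <- d[1] * d[2]; m <- perChan * d[4]
  chanSum <- function(a) {
    a <- aperm(a, c(1L, 2L, 4L, 3L))
    dim(a) <- c(m, C)
    colSums(a)
  }
  dShift <- chanSum(dOut)
  dScale <- chanSum(dOut * xhat)
  inv <- 1 / sqrt(batchVar + epsilon)
  g <- dOut * as.vector(rep(scale, each = perChan))
  gs <- chanSum(g)
  gxs <- chanSum(g * xhat)
  dX <- (g - as.vector(rep(gs / m, each = perChan)) -
           xhat * as.vector(rep(gxs / m, each = perChan))) *
    as.vector(rep(inv, each = perChan))
  list(dInput = dX, dScale = dScale, dShift = dShift)
}

#' Average pooling
#'
#' Replaces each non-overlapping `window` x `window` block by its
#' arithmetic mean (mean pooling with an all-ones averaging matrix). Input
#' spatial dimensions must be divisible by the window; non-divisible inputs
#' raise an error rather than being silently cropped.
#'
#' @param input feature maps (matrix promoted).
#' @param window positive integer pooling window `k_p`.
#' @return Pooled feature maps, spatial dims divided by `window`.
#' @examples
#' avgPool(matrix(1:4, 2, byrow = TRUE), 2)
#' @export
avgPool <- function(input, window) {
  w <- as.integer(window)
  if (w < 1L) stop("window must be >= 1", call. = FALSE)
  x <- asFeatureMap(input)
  d <- dim(x)
  if (w == 1L) return(input)
  if (any(d[1:2] %% w != 0L))
    stop(sprintf("spatial dims (%d x %d) not divisible by window %d",
                 d[1], d[2], w), call. = FALSE)
  Ho <- d[1] %/% w; Wo <- d[2] %/% w
  dim(x) <- c(w, Ho * d[2] * d[3] * d[4])
  s1 <- colMeans(x)
  dim(s1) <- c(Ho, d[2], d[3], d[4])
  s1 <- aperm(s1, c(2L, 1L, 3L, 4L))
  dim(s1) <- c(w, Wo * Ho * d[3] * d[4])
  s2 <- colMeans(s1)
  dim(s2) <- c(Wo, Ho, d[3], d[4])
  dropLike(aperm(s2, c(2L, 1L, 3L, 4L)), input)
}

avgPoolBackward <- function(dOut, window) {
  w <- as.integer(window)
  if (w == 1L) return(dOut)
  d <- dim(dOut)
  dOut[rep(seq_len(d[1]), each = w), rep(seq_len(d[2]), each = w), , ,
       drop = FALSE] / w^2
}

#' Per-pixel softmax
#'
#' Converts per-pixel class scores into probabilities,
#' `p_j = exp(v_j) / sum_k exp(v_k)`, computed with max-shift
#' stabilization so arbitrarily large scores cannot overflow. The
#' normalizer (the softmax partition function) guarantees each pixel's
#' probabilities are non-negative and sum to one.
#'
#' @param scores array `(H, W, U)` or `(H, W, U, N)` of per-pixel class
#'   scores, U >= 2.
#' @return Probabilities, same shape as `scores`.
#' @examples
#' pixelSoftmax(array(c(1, 0, 0), c(1, 1, 3)))
#' @export
pixelSoftmax <- function(scores) {
  d <- dim(scores)
  if (is.null(d) || length(d) < 3L)
    stop("scores must be (H, W, U[, N])", call. = FALSE)
  if (d[3] < 2L) stop("need at least two classes", call. = FALSE)
  x <- asFeatureMap(scores)
  sm <- softmaxMatrix(x)
  probs <- sm$probs
  dim(probs) <- c(dim(x)[3], dim(x)[1], dim(x)[2], dim(x)[4])
  dropLike(aperm(probs, c(2L, 3L, 1L, 4L)), scores)
}

# Class-major (U x nPixels) stabilized softmax; column order is the
# column-major pixel order (row, col, sample).
softmaxMatrix <- function(x) {
  d <- dim(x)
  U <- d[3]
  ap <- aperm(x, c(3L, 1L, 2L, 4L))
  dim(ap) <- c(U, d[1] * d[2] * d[4])
  mx <- ap[1L, ]
  for (j in seq_len(U)[-1L]) mx <- pmax(mx, ap[j, ])
  e <- exp(ap - rep(mx, each = U))
  z <- colSums(e)
  list(probs = e / rep(z, each = U), partition = z)
}

#' Predict per-pixel labels from a probability map
#'
#' Assigns each pixel the class of maximal probability (`argmax`); ties
#' break to the lowest class index. Labels are 0-based: 0 surrounding,
#' 1 central gland, 2 marginal gland in the default three-class setting.
#'
#' @param probmap array `(H, W, U)` or `(H, W, U, N)`.
#' @return Integer label matrix `(H, W)` (or array `(H, W, N)`).
#' @examples
#' predictLabels(array(c(0.1, 0.7, 0.2), c(1, 1, 3)))
#' @export
predictLabels <- function(probmap) {
  d <- dim(probmap)
  if (is.null(d) || length(d) < 3L)
    stop("probmap must be (H, W, U[, N])", call. = FALSE)
  x <- asFeatureMap(probmap)
  dd <- dim(x)
  ap <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(ap) <- c(dd[1] * dd[2] * dd[4], dd[3])
  lab <- max.col(ap, ties.method = "first") - 1L
  if (length(d) == 3L) {
    dim(lab) <- dd[1:2]
  } else {
    dim(lab) <- c(dd[1], dd[2], dd[4])
  }
  lab
}

#' Mean cross-entropy segmentation loss
#'
#' The negative mean, over all `c x d` image pixels (and all samples), of
#' the log-probability assigned to each pixel's true class. Probabilities
#' are clipped away from zero before the log so the loss is always finite
#' and non-negative.
#'
#' @param probmap probability array `(H, W, U[, N])`.
#' @param targets integer label mask `(H, W[, N])` with 0-based classes, or
#'   a one-hot array shaped like `probmap`.
#' @param classWeights optional per-class weights; the weighted mean is
#'   normalized by the total weight.
#' @return Scalar loss (>= 0).
#' @examples
#' p <- array(rep(1 / 3, 12), c(2, 2, 3))
#' crossEntropyLoss(p, matrix(0L, 2, 2))  # log(3)
#' @export
crossEntropyLoss <- function(probmap, targets, classWeights = NULL) {
  x <- asFeatureMap(probmap)
  d <- dim(x)
  U <- d[3]
  if (identical(dim(targets), dim(probmap)) && length(dim(targets)) >= 3L) {
    targets <- predictOneHotToLabels(asFeatureMap(targets))
  } else {
    targets <- if (is.matrix(targets)) array(targets, c(dim(targets), 1L))
               else targets
  }
  if (!all(dim(targets) == d[c(1, 2, 4)]))
    stop("probmap and targets pixel grids differ", call. = FALSE)
  lab <- as.integer(targets)
  if (any(lab < 0L | lab >= U))
    stop("target labels outside [0, U)", call. = FALSE)
  pm <- aperm(x, c(3L, 1L, 2L, 4L))
  dim(pm) <- c(U, length(lab))
  pTrue <- pm[cbind(lab + 1L, seq_along(lab))]
  nll <- -log(pmax(pTrue, 1e-12))
  if (is.null(classWeights) || !length(classWeights)) return(mean(nll))
  wt <- classWeights[lab + 1L]
  sum(wt * nll) / sum(wt)
}

predictOneHotToLabels <- function(oneHot) {
  d <- dim(oneHot)
  ap <- aperm(oneHot, c(1L, 2L, 4L, 3L))
  dim(ap) <- c(d[1] * d[2] * d[4], d[3])
  if (any(abs(rowSums(ap) - 1) > 1e-6))
    stop("one-hot targets must sum to 1 per pixel", call. = FALSE)
  lab <- max.col(ap, ties.method = "first") - 1L
  array(lab, c(d[1], d[2], d[4]))
}

#' Transposed-convolution (deconvolution) upsampling
#'
#' Learnable upsampling for the decoder: with kernels of spatial size equal
#' to the stride the output grid is exactly `stride` times the input grid
#' and the operation is the exact adjoint of the stride-`stride` valid
#' convolution with the same kernel array, i.e.
#' `<convForward(x, K), y> == <x, deconvUpsample(y, K)>`.
#'
#' @param input feature maps with `inC` channels.
#' @param kernels array `(kh, kw, outC, inC)`; `kh == kw == stride`.
#' @param bias length-`outC` numeric or NULL.
#' @param stride upsampling factor, >= 2.
#' @return Feature maps of spatial size `stride` times the input, with
#'   `outC` channels.
#' @examples
#' deconvUpsample(matrix(3), array(1, c(2, 2, 1, 1)), stride = 2)
#' @export
deconvUpsample <- function(input, kernels, bias = NULL, stride = 2L) {
  s <- as.integer(stride)
  if (s < 2L) stop("stride must be >= 2 for upsampling", call. = FALSE)
  y <- asFeatureMap(input)
  k <- asKernel4(kernels)
  kd <- dim(k)
  if (kd[1] != s || kd[2] != s)
    stop("deconv kernels must be stride x stride", call. = FALSE)
  d <- dim(y)
  if (d[3] != kd[4])
    stop(sprintf("input has %d channels but kernels expect %d",
                 d[3], kd[4]), call. = FALSE)
  outC <- kd[3]
  Ymat <- aperm(y, c(3L, 1L, 2L, 4L))
  dim(Ymat) <- c(d[3], d[1] * d[2] * d[4])
  Km <- k; dim(Km) <- c(s * s * outC, kd[4])
  T <- Km %*% Ymat
  dim(T) <- c(s, s, outC, d[1], d[2], d[4])
  out <- array(0, c(s * d[1], s * d[2], outC, d[4]))
  for (dh in seq_len(s)) for (dw in seq_len(s)) {
    sl <- T[dh, dw, , , , , drop = FALSE]
    dim(sl) <- c(outC, d[1], d[2], d[4])
    out[seq.int(dh, by = s, length.out = d[1]),
        seq.int(dw, by = s, length.out = d[2]), , ] <-
      aperm(sl, c(2L, 3L, 1L, 4L))
  }
  if (!is.null(bias)) {
    if (length(bias) != outC)
      stop("bias length must equal the output channel count", call. = FALSE)
    out <- out + rep(bias, each = s * d[1] * s * d[2])
  }
  dropLike(out, input)
}

deconvBackward <- function(dOut, input, kernels, stride) {
  s <- as.integer(stride)
  y <- asFeatureMap(input)
  k <- asKernel4(kernels)
  kd <- dim(k)
  outC <- kd[3]
  d <- dim(y)
  dT <- array(0, c(s, s, outC, d[1], d[2], d[4]))
  for (dh in seq_len(s)) for (dw in seq_len(s)) {
    sl <- dOut[seq.int(dh, by = s, length.out = d[1]),
               seq.int(dw, by = s, length.out = d[2]), , , drop = FALSE]
    dT[dh, dw, , , , ] <- aperm(sl, c(3L, 1L, 2L, 4L))
  }
  dim(dT) <- c(s * s * outC, d[1] * d[2] * d[4])
  Ymat <- aperm(y, c(3L, 1L, 2L, 4L))
  dim(Ymat) <- c(d[3], d[1] * d[2] * d[4])
  Km <- k; dim(Km) <- c(s * s * outC, kd[4])
  dY <- crossprod(Km, dT)
  dim(dY) <- c(d[3], d[1], d[2], d[4])
  dK <- dT %*% t(Ymat)
  dim(dK) <- kd
  dBias <- rowSums(colSums(dOut, dims = 2L))
  list(dInput = aperm(dY, c(2L, 3L, 1L, 4L)), dKernels = dK, dBias = dBias)
}
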