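# PSSNET: a small encoder-decoder segmentation network. The encoder
# extracts features with conv -> batch norm -> ReLU blocks and mean
# pooling; the decoder restores pixel resolution with stride-2 transposed
# convolutions; a 1x1 convolution and per-pixel softmax emit the
# three-class probability map. Training minimizes the mean per-pixel
# cross-entropy by mini-batch gradient descent.

# Input intensities are on an 8-bit-like scale; a fixed affine rescale
# keeps early activations O(1).
INPUT_SCALE <- 255

heKernel <- function(kh, kw, c3, c4, fanIn) {
  array(stats::rnorm(kh * kw * c3 * c4, 0, sqrt(2 / fanIn)),
        c(kh, kw, c3, c4))
}

#' Build an untrained PSSNET model
#'
#' Constructs the encoder-decoder described by `config` and initializes
#' kernels with seeded He-scaled Gaussian draws, biases and batch-norm
#' shifts at 0, batch-norm scales at 1, and running statistics at
#' (mean 0, variance 1). Two builds from the same config (and seed) are
#' identical; the caller's RNG stream is untouched.
#'
#' @param config a [NetworkConfig-class].
#' @return An untrained [PSSNet-class] model.
#' @examples
#' net <- buildPSSNet(NetworkConfig())
#' net
#' @export
buildPSSNet <- function(config = NetworkConfig()) {
  validObject(config)
  k <- config@kernelSize
  pw <- config@poolWindow
  encC <- config@encoderChannels
  decC <- config@decoderChannels
  withSeed(config@seed, {
    enc <- vector("list", length(encC))
    cin <- 1L
    for (i in seq_along(encC)) {
      cout <- encC[i]
      enc[[i]] <- list(K = heKernel(k, k, cin, cout, k * k * cin),
                       b = rep(0, cout), gamma = rep(1, cout),
                       beta = rep(0, cout))
      cin <- cout
    }
    dec <- vector("list", length(decC))
    for (j in seq_along(decC)) {
      cout <- decC[j]
      dec[[j]] <- list(K = heKernel(pw, pw, cout, cin, cin),
                       b = rep(0, cout), gamma = rep(1, cout),
                       beta = rep(0, cout))
      cin <- cout
    }
    head <- list(K = heKernel(1L, 1L, cin, config@nClasses, cin),
                 b = rep(0, config@nClasses))
    params <- list(enc = enc, dec = dec, head = head)
    bnState <- list(
      enc = lapply(encC, function(ch) list(mean = rep(0, ch),
                                           var = rep(1, ch))),
      dec = lapply(decC, function(ch) list(mean = rep(0, ch),
                                           var = rep(1, ch))))
    new("PSSNet", config = config, params = params, bnState = bnState,
        trained = FALSE,
        trainingLog = data.frame(epoch = integer(), meanLoss = numeric()))
  })
}

# Shared conv-with-cache used by the encoder blocks and the 1x1 head.
convFwdCached <- function(h, K, b, padding) {
  kd <- dim(K)
  pad <- if (padding == "same") samePad(kd[1]) else 0L
  ic <- im2col(h, kd[1], kd[2], pad, pad, 1L)
  Km <- K; dim(Km) <- c(kd[1] * kd[2] * kd[3], kd[4])
  Y <- crossprod(Km, ic$P) + b
  dim(Y) <- c(kd[4], ic$Ho, ic$Wo, dim(h)[4])
  list(out = aperm(Y, c(2L, 3L, 1L, 4L)), ic = ic)
}

# Forward pass over a (H, W, 1, N) stack. Returns softmax probabilities in
# class-major matrix form plus everything the backward pass needs.
netForward <- function(params, bnState, x, cfg, training,
                       keepCache = FALSE) {
  nEnc <- length(cfg@encoderChannels)
  nDec <- length(cfg@decoderChannels)
  caches <- list(enc = vector("list", nEnc), dec = vector("list", nDec))
  h <- x / INPUT_SCALE
  for (i in seq_len(nEnc)) {
    p <- params$enc[[i]]
    cf <- convFwdCached(h, p$K, p$b, "same")
    st <- bnState$enc[[i]]
    bn <- batchNorm(cf$out, p$gamma, p$beta, cfg@bnEpsilon, training,
                    st$mean, st$var, cfg@bnMomentum)
    if (training)
      bnState$enc[[i]] <- list(mean = bn$runningMean, var = bn$runningVar)
    r <- relu(bn$output)
    if (keepCache)
      caches$enc[[i]] <- list(ic = cf$ic, xhat = bn$normalized,
                              batchVar = bn$batchVar, preRelu = bn$output)
    h <- if (i < nEnc) avgPool(r, cfg@poolWindow) else r
  }
  for (j in seq_len(nDec)) {
    p <- params$dec[[j]]
    if (keepCache) decIn <- h
    up <- deconvUpsample(h, p$K, p$b, stride = cfg@poolWindow)
    st <- bnState$dec[[j]]
    bn <- batchNorm(up, p$gamma, p$beta, cfg@bnEpsilon, training,
                    st$mean, st$var, cfg@bnMomentum)
    if (training)
      bnState$dec[[j]] <- list(mean = bn$runningMean, var = bn$runningVar)
    h <- relu(bn$output)
    if (keepCache)
      caches$dec[[j]] <- list(input = decIn, xhat = bn$normalized,
                              batchVar = bn$batchVar, preRelu = bn$output)
  }
  cf <- convFwdCached(h, params$head$K, params$head$b, "same")
  if (keepCache) caches$head <- list(ic = cf$ic)
  sm <- softmaxMatrix(cf$out)
  list(probs = sm$probs, scoreDim = dim(cf$out), caches = caches,
       bnState = bnState)
}

# One loss + gradient evaluation on a batch (labels: (H, W, N), 0-based).
netLossGrad <- function(params, bnState, x, labels, cfg) {
  fw <- netForward(params, bnState, x, cfg, training = TRUE,
                   keepCache = TRUE)
  U <- cfg@nClasses
  lab <- as.integer(labels)
  nPix <- length(lab)
  pTrue <- fw$probs[cbind(lab + 1L, seq_len(nPix))]
  wts <- cfg@classWeights
  if (length(wts)) {
    w <- wts[lab + 1L]
    wSum <- sum(w)
    loss <- sum(w * -log(pmax(pTrue, 1e-12))) / wSum
  } else {
    loss <- mean(-log(pmax(pTrue, 1e-12)))
  }
  dS <- fw$probs
  dS[cbind(lab + 1L, seq_len(nPix))] <- dS[cbind(lab + 1L,
                                                 seq_len(nPix))] - 1
  if (length(wts)) {
    dS <- dS * rep(w / wSum, each = U)
  } else {
    dS <- dS / nPix
  }
  dim(dS) <- c(U, fw$scoreDim[1], fw$scoreDim[2], fw$scoreDim[4])
  dh <- aperm(dS, c(2L, 3L, 1L, 4L))

  grads <- list(enc = vector("list", length(params$enc)),
                dec = vector("list", length(params$dec)), head = NULL)
  cb <- convBackward(dh, params$head$K, fw$caches$head$ic)
  grads$head <- list(K = cb$dKernels, b = cb$dBias)
  dh <- cb$dInput
  for (j in rev(seq_along(params$dec))) {
    p <- params$dec[[j]]
    ch <- fw$caches$dec[[j]]
    dh <- dh * (ch$preRelu > 0)
    bb <- batchNormBackward(dh, ch$xhat, p$gamma, ch$batchVar,
                            cfg@bnEpsilon)
    db <- deconvBackward(bb$dInput, ch$input, p$K, cfg@poolWindow)
    grads$dec[[j]] <- list(K = db$dKernels, b = db$dBias,
                           gamma = bb$dScale, beta = bb$dShift)
    dh <- db$dInput
  }
  for (i in rev(seq_along(params$enc))) {
    p <- params$enc[[i]]
    ch <- fw$caches$enc[[i]]
    if (i < length(params$enc)) dh <- avgPoolBackward(dh, cfg@poolWindow)
    dh <- dh * (ch$preRelu > 0)
    bb <- batchNormBackward(dh, ch$xhat, p$gamma, ch$batchVar,
                            cfg@bnEpsilon)
    cb <- convBackward(bb$dInput, p$K, ch$ic)
    grads$enc[[i]] <- list(K = cb$dKernels, b = cb$dBias,
                           gamma = bb$dScale, beta = bb$dShift)
    dh <- cb$dInput
  }
  list(loss = loss, grads = grads, bnState = fw$bnState)
}

# Rebuild the nested parameter list from a flat numeric vector (depth-first
# order, matching unlist()).
rebuildParams <- function(theta, skeleton) {
  i <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- theta[i + seq_len(n)]
    i <<- i + n
    dim(out) <- dim(s)
    out
  }
  rec(skeleton)
}

stackDataset <- function(images, masks = NULL) {
  dims <- dim(images[[1]])
  if (!all(vapply(images, function(m) all(dim(m) == dims), TRUE)))
    stop("all images must share dimensions", call. = FALSE)
  n <- length(images)
  x <- array(unlist(images, use.names = FALSE), c(dims, 1L, n))
  x <- aperm(x, c(1L, 2L, 3L, 4L))  # already (H, W, 1, N)
  y <- NULL
  if (!is.null(masks))
    y <- array(as.integer(unlist(masks, use.names = FALSE)), c(dims, n))
  list(x = x, y = y, n = n)
}

#' Train a PSSNET model
#'
#' Mini-batch gradient descent on the mean per-pixel cross-entropy loss.
#' Batches are reshuffled every epoch from a seed derived from the config
#' seed, so the whole run is bit-reproducible; a trailing batch of a single
#' sample is merged into its predecessor so training-mode batch
#' normalization always sees at least two samples.
#'
#' @param images list of intensity matrices (all the same size, matching
#'   `config@inputSize`).
#' @param masks list of integer label masks paired with `images`.
#' @param config a [NetworkConfig-class].
#' @param model optionally, an existing [PSSNet-class] to continue
#'   training; by default a fresh model is built from `config`.
#' @return A trained [PSSNet-class]; `trainingLog(model)` records the mean
#'   training loss per epoch.
#' @examples
#' \donttest{
#' ph <- lapply(1:8, function(i) generatePhantom(PhantomParams(), i))
#' net <- trainPSSNet(lapply(ph, `[[`, "image"), lapply(ph, `[[`, "mask"),
#'                    NetworkConfig(epochs = 1L))
#' }
#' @export
trainPSSNet <- function(images, masks, config = NetworkConfig(),
                        model = NULL) {
  if (!length(images)) stop("dataset is empty", call. = FALSE)
  if (length(images) != length(masks))
    stop("images and masks must pair up", call. = FALSE)
  validObject(config)
  ds <- stackDataset(images, masks)
  if (!all(dim(ds$x)[1:2] == config@inputSize))
    stop("image dimensions do not match config@inputSize", call. = FALSE)
  if (is.null(model)) model <- buildPSSNet(config)
  params <- model@params
  bnState <- model@bnState
  theta <- unlist(params, use.names = FALSE)
  mVec <- numeric(length(theta))
  vVec <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8
  t <- 0L
  log <- data.frame(epoch = integer(), meanLoss = numeric())
  for (epoch in seq_len(config@epochs)) {
    ord <- withSeed(deriveSeed(config@seed, paste0("epoch", epoch)),
                    sample.int(ds$n))
    starts <- seq.int(1L, ds$n, by = config@batchSize)
    batches <- lapply(starts, function(s)
      ord[s:min(s + config@batchSize - 1L, ds$n)])
    nb <- length(batches)
    if (nb > 1L && length(batches[[nb]]) == 1L) {
      batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
      batches[[nb]] <- NULL
    }
    epochLoss <- 0; epochN <- 0L
    for (idx in batches) {
      xb <- ds$x[, , , idx, drop = FALSE]
      yb <- ds$y[, , idx, drop = FALSE]
      lg <- netLossGrad(params, bnState, xb, yb, config)
      bnState <- lg$bnState
      gVec <- unlist(lg$grads, use.names = FALSE)
      if (config@optimizer == "adam") {
        t <- t + 1L
        mVec <- b1 * mVec + (1 - b1) * gVec
        vVec <- b2 * vVec + (1 - b2) * gVec^2
        mHat <- mVec / (1 - b1^t)
        vHat <- vVec / (1 - b2^t)
        theta <- theta - config@learningRate * mHat /
          (sqrt(vHat) + adamEps)
      } else {
        theta <- theta - config@learningRate * gVec
      }
      params <- rebuildParams(theta, params)
      epochLoss <- epochLoss + lg$loss * length(idx)
      epochN <- epochN + length(idx)
    }
    log <- rbind(log, data.frame(epoch = epoch,
                                 meanLoss = epochLoss / epochN))
  }
  new("PSSNet", config = config, params = params, bnState = bnState,
      trained = TRUE, trainingLog = log)
}

#' Segment an image with a PSSNET model
#'
#' Runs the forward pass in inference mode (batch normalization uses the
#' stored running statistics, so repeated calls give identical output) and
#' converts the per-pixel probability map to a label mask by argmax.
#'
#' @param model a [PSSNet-class].
#' @param image intensity matrix whose dimensions match the model's
#'   configured input size.
#' @return A list with `mask` (integer matrix, labels 0/1/2) and `probs`
#'   (array `(H, W, U)` of per-pixel class probabilities).
#' @examples
#' net <- buildPSSNet(NetworkConfig())
#' ph <- generatePhantom(PhantomParams(), seed = 1)
#' seg <- segmentImage(net, ph$image)
#' table(seg$mask)
#' @export
segmentImage <- function(model, image) {
  stopifnot(is(model, "PSSNet"))
  stopIfNot2D(image, "image")
  cfg <- model@config
  if (!all(dim(image) == cfg@inputSize))
    stop(sprintf("image is %dx%d but the model expects %dx%d",
                 nrow(image), ncol(image), cfg@inputSize[1],
                 cfg@inputSize[2]), call. = FALSE)
  x <- array(image, c(dim(image), 1L, 1L))
  fw <- netForward(model@params, model@bnState, x, cfg, training = FALSE)
  probs <- fw$probs
  dim(probs) <- c(cfg@nClasses, fw$scoreDim[1], fw$scoreDim[2])
  probs <- aperm(probs, c(2L, 3L, 1L))
  list(mask = predictLabels(probs), probs = probs)
}

#' Accessors for PSSNet models
#'
#' `trainingLog()` returns the per-epoch mean-loss data.frame;
#' `modelConfig()` the [NetworkConfig-class] a model was built with.
#'
#' @param model a [PSSNet-class].
#' @return See description.
#' @export
trainingLog <- function(model) model@trainingLog

#' @rdname trainingLog
#' @export
modelConfig <- function(model) model@config

#' Save or load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the configuration,
#' parameter tensors, running batch-norm statistics and training log.
#'
#' @param model a [PSSNet-class].
#' @param path checkpoint file path.
#' @return `loadModel` returns the [PSSNet-class]; `saveModel` its path,
#'   invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PSSNet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "PSSNet")) stop("not a PSSNet checkpoint", call. = FALSE)
  model
}
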