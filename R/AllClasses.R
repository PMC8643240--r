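#' @import methods
NULL

#' Parameters of the synthetic prostate phantom
#'
#' An S4 container for the geometry, intensity and noise model of the
#' synthetic axial T2WI-like prostate slice. The gland is modelled as an
#' ellipse (transverse x antero-posterior axes, in mm) containing a
#' concentric central zone; the remaining gland ring is the marginal
#' (peripheral) zone. Class-mean intensities are on an 8-bit-like scale with
#' the marginal zone brightest, as on T2-weighted imaging, and lesions dark
#' ("low signal").
#'
#' @slot imageHeight,imageWidth image size in pixels.
#' @slot pixelSpacing mm per pixel (isotropic).
#' @slot glandTransverseAxis,glandAPAxis full axis lengths of the outer
#'   gland ellipse, in mm (defaults 40 and 20).
#' @slot centralFraction axis scale of the central zone relative to the
#'   whole gland, strictly in (0, 1) so the marginal zone is non-empty.
#' @slot intensityMeans named numeric vector with entries `surrounding`,
#'   `central`, `marginal`, `lesion` (arbitrary intensity units).
#' @slot noiseSD standard deviation of the additive zero-mean Gaussian
#'   noise, in intensity units.
#' @slot lesionProbabilityGivenCancer probability that a cancer case in a
#'   simulated cohort receives a visible lesion.
#' @slot lesionRadiusRange length-2 numeric, pixel radius range from which
#'   cohort lesions are drawn uniformly.
#'
#' @seealso [generatePhantom()], [generateCohort()]
#' @export
setClass("PhantomParams", representation(
  imageHeight = "integer",
  imageWidth = "integer",
  pixelSpacing = "numeric",
  glandTransverseAxis = "numeric",
  glandAPAxis = "numeric",
  centralFraction = "numeric",
  intensityMeans = "numeric",
  noiseSD = "numeric",
  lesionProbabilityGivenCancer = "numeric",
  lesionRadiusRange = "numeric"
))

setValidity("PhantomParams", function(object) {
  msg <- character()
  need <- c("surrounding", "central", "marginal", "lesion")
  if (object@imageHeight < 1L || object@imageWidth < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be > 0")
  if (object@glandTransverseAxis <= 0 || object@glandAPAxis <= 0)
    msg <- c(msg, "gland axis lengths must be > 0")
  if (object@glandTransverseAxis / object@pixelSpacing > object@imageWidth ||
      object@glandAPAxis / object@pixelSpacing > object@imageHeight)
    msg <- c(msg, "gland axes exceed the image extent")
  if (!(object@centralFraction > 0 && object@centralFraction < 1))
    msg <- c(msg, "centralFraction must lie strictly in (0, 1)")
  if (!all(need %in% names(object@intensityMeans)))
    msg <- c(msg, sprintf("intensityMeans must name %s",
                          paste(need, collapse = ", ")))
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@lesionProbabilityGivenCancer < 0 ||
      object@lesionProbabilityGivenCancer > 1)
    msg <- c(msg, "lesionProbabilityGivenCancer must be in [0, 1]")
  if (length(object@lesionRadiusRange) != 2L ||
      any(object@lesionRadiusRange <= 0) ||
      diff(object@lesionRadiusRange) < 0)
    msg <- c(msg, "lesionRadiusRange must be an increasing positive pair")
  if (length(msg)) msg else TRUE
})

#' Construct PhantomParams
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param pixelSpacing mm per pixel.
#' @param glandTransverseAxis,glandAPAxis gland axis lengths in mm.
#' @param centralFraction central-zone axis scale in (0, 1).
#' @param intensityMeans named vector of class-mean intensities.
#' @param noiseSD Gaussian noise standard deviation.
#' @param lesionProbabilityGivenCancer lesion probability for cancer cases.
#' @param lesionRadiusRange pixel radius range for cohort lesions.
#' @return A validated [PhantomParams-class] object.
#' @examples
#' p <- PhantomParams()
#' p
#' @export
PhantomParams <- function(imageHeight = 64L, imageWidth = 64L,
                          pixelSpacing = 1,
                          glandTransverseAxis = 40, glandAPAxis = 20,
                          centralFraction = 0.55,
                          intensityMeans = c(surrounding = 90, central = 140,
                                             marginal = 190, lesion = 70),
                          noiseSD = 10,
                          lesionProbabilityGivenCancer = 0.8,
                          lesionRadiusRange = c(3, 8)) {
  new("PhantomParams",
      imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth),
      pixelSpacing = pixelSpacing,
      glandTransverseAxis = glandTransverseAxis,
      glandAPAxis = glandAPAxis,
      centralFraction = centralFraction,
      intensityMeans = intensityMeans,
      noiseSD = noiseSD,
      lesionProbabilityGivenCancer = lesionProbabilityGivenCancer,
      lesionRadiusRange = as.numeric(lesionRadiusRange))
}

setMethod("show", "PhantomParams", function(object) {
  cat("PhantomParams\n")
  cat(sprintf("  image: %d x %d px @ %.3g mm/px\n", object@imageHeight,
              object@imageWidth, object@pixelSpacing))
  cat(sprintf("  gland: %.3g x %.3g mm (central fraction %.2f)\n",
              object@glandTransverseAxis, object@glandAPAxis,
              object@centralFraction))
  cat(sprintf("  intensities: %s; noise sd %.3g\n",
              paste(sprintf("%s=%g", names(object@intensityMeans),
                            object@intensityMeans), collapse = ", "),
              object@noiseSD))
})

#' Network architecture and training configuration
#'
#' Configuration of the PSSNET encoder-decoder: an encoder of
#' conv (3x3, same padding) -> batch norm -> ReLU blocks with 2x2 average
#' pooling after all but the last block, a decoder of stride-2 transposed
#' convolution -> batch norm -> ReLU stages, and a final 1x1 convolution to
#' `nClasses` channels followed by a per-pixel softmax.
#'
#' @slot encoderChannels integer vector of encoder block widths.
#' @slot decoderChannels integer vector of decoder stage widths; its length
#'   fixes the number of stride-2 upsampling stages, which must undo the
#'   encoder's pooling exactly.
#' @slot kernelSize spatial size of encoder kernels.
#' @slot poolWindow average pooling window (`k_p`).
#' @slot nClasses number of output classes (3: surrounding, central,
#'   marginal).
#' @slot inputSize length-2 integer, expected image height and width.
#' @slot learningRate,epochs,batchSize,optimizer training hyperparameters.
#' @slot seed master seed for initialization and batch shuffling.
#' @slot bnEpsilon numerical-stability constant in the batch-norm
#'   denominator.
#' @slot bnMomentum exponential-moving-average weight for running batch
#'   statistics.
#' @slot classWeights optional per-class loss weights (length `nClasses`);
#'   `NA_real_` of length 0 disables weighting.
#' @export
setClass("NetworkConfig", representation(
  encoderChannels = "integer",
  decoderChannels = "integer",
  kernelSize = "integer",
  poolWindow = "integer",
  nClasses = "integer",
  inputSize = "integer",
  learningRate = "numeric",
  epochs = "integer",
  batchSize = "integer",
  optimizer = "character",
  seed = "integer",
  bnEpsilon = "numeric",
  bnMomentum = "numeric",
  classWeights = "numeric"
))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  nPool <- length(object@encoderChannels) - 1L
  if (length(object@decoderChannels) != nPool)
    msg <- c(msg, "decoder stage count must equal the number of pooled encoder blocks so upsampling restores the input dims")
  factor <- object@poolWindow^nPool
  if (any(object@inputSize %% factor != 0L))
    msg <- c(msg, sprintf("inputSize must be divisible by %d", factor))
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@epochs < 1L || object@batchSize < 1L)
    msg <- c(msg, "epochs and batchSize must be >= 1")
  if (object@bnEpsilon <= 0) msg <- c(msg, "bnEpsilon must be > 0")
  if (length(object@classWeights) &&
      length(object@classWeights) != object@nClasses)
    msg <- c(msg, "classWeights must have one entry per class")
  if (!object@optimizer %in% c("adam", "sgd"))
    msg <- c(msg, "optimizer must be 'adam' or 'sgd'")
  if (length(msg)) msg else TRUE
})

#' Construct a NetworkConfig
#'
#' @param encoderChannels encoder block widths.
#' @param decoderChannels decoder stage widths.
#' @param kernelSize encoder kernel size.
#' @param poolWindow average-pooling window.
#' @param nClasses output class count.
#' @param inputSize expected image height and width.
#' @param learningRate,epochs,batchSize,optimizer training hyperparameters.
#' @param seed master seed.
#' @param bnEpsilon,bnMomentum batch-norm constants.
#' @param classWeights optional per-class loss weights.
#' @return A validated [NetworkConfig-class].
#' @examples
#' cfg <- NetworkConfig(epochs = 2L)
#' cfg
#' @export
NetworkConfig <- function(encoderChannels = c(16L, 32L, 64L),
                          decoderChannels = c(32L, 16L),
                          kernelSize = 3L, poolWindow = 2L, nClasses = 3L,
                          inputSize = c(64L, 64L),
                          learningRate = 1e-3, epochs = 10L, batchSize = 8L,
                          optimizer = "adam", seed = 1L,
                          bnEpsilon = 1e-5, bnMomentum = 0.1,
                          classWeights = numeric()) {
  new("NetworkConfig",
      encoderChannels = as.integer(encoderChannels),
      decoderChannels = as.integer(decoderChannels),
      kernelSize = as.integer(kernelSize),
      poolWindow = as.integer(poolWindow),
      nClasses = as.integer(nClasses),
      inputSize = as.integer(inputSize),
      learningRate = learningRate,
      epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      optimizer = optimizer,
      seed = as.integer(seed),
      bnEpsilon = bnEpsilon,
      bnMomentum = bnMomentum,
      classWeights = as.numeric(classWeights))
}

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig (PSSNET encoder-decoder)\n")
  cat(sprintf("  encoder: %s (%dx%d kernels, pool %d)\n",
              paste(object@encoderChannels, collapse = "-"),
              object@kernelSize, object@kernelSize, object@poolWindow))
  cat(sprintf("  decoder: %s (stride-2 transposed conv)\n",
              paste(object@decoderChannels, collapse = "-")))
  cat(sprintf("  input %dx%d -> %d classes\n", object@inputSize[1],
              object@inputSize[2], object@nClasses))
  cat(sprintf("  %s, lr %.3g, %d epochs, batch %d, seed %d\n",
              object@optimizer, object@learningRate, object@epochs,
              object@batchSize, object@seed))
})

#' A PSSNET model
#'
#' Holds the layer parameters (kernels, biases, batch-norm scales/shifts),
#' the running batch-norm statistics used at inference, the configuration
#' the model was built with, and the per-epoch training log.
#'
#' @slot config the [NetworkConfig-class] used to build the model.
#' @slot params named list of per-layer parameter arrays.
#' @slot bnState named list of running means/variances per batch-norm layer.
#' @slot trained logical; `TRUE` after [trainPSSNet()].
#' @slot trainingLog data.frame with columns `epoch` and `meanLoss`.
#' @seealso [buildPSSNet()], [trainPSSNet()], [segmentImage()]
#' @export
setClass("PSSNet", representation(
  config = "NetworkConfig",
  params = "list",
  bnState = "list",
  trained = "logical",
  trainingLog = "data.frame"
))

setMethod("show", "PSSNet", function(object) {
  cat("PSSNet model\n")
  nPar <- length(unlist(object@params))
  cat(sprintf("  %d parameters, %s\n", nPar,
              if (object@trained) "trained" else "untrained"))
  show(object@config)
  if (nrow(object@trainingLog)) {
    lastRow <- object@trainingLog[nrow(object@trainingLog), ]
    cat(sprintf("  final mean loss %.5f after %d epoch(s)\n",
                lastRow$meanLoss, lastRow$epoch))
  }
})

#' Segmentation-quality metrics for one prediction/reference pair
#'
#' @slot dsc Dice similarity coefficient in \[0, 1\] on filled regions.
#' @slot hd symmetric Hausdorff distance (pixels, or mm when a pixel
#'   spacing was supplied) on boundary pixel sets.
#' @slot hdForward,hdBackward the two directed Hausdorff distances whose
#'   maximum is `hd`.
#' @slot perClass named per-class Dice values (empty in foreground mode).
#' @slot units distance units, `"px"` or `"mm"`.
#' @export
setClass("SegMetrics", representation(
  dsc = "numeric",
  hd = "numeric",
  hdForward = "numeric",
  hdBackward = "numeric",
  perClass = "numeric",
  units = "character"
))

setValidity("SegMetrics", function(object) {
  msg <- character()
  if (object@dsc < 0 || object@dsc > 1) msg <- c(msg, "dsc must be in [0, 1]")
  if (object@hd < 0) msg <- c(msg, "hd must be >= 0")
  mx <- max(object@hdForward, object@hdBackward)
  if (!(object@hd == mx || abs(object@hd - mx) <= 1e-12))
    msg <- c(msg, "hd must equal max(hdForward, hdBackward)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SegMetrics", function(object) {
  cat(sprintf("SegMetrics: DSC %.4f, HD %.4f %s (fwd %.4f, bwd %.4f)\n",
              object@dsc, object@hd, object@units, object@hdForward,
              object@hdBackward))
  if (length(object@perClass))
    cat("  per-class DSC:",
        paste(sprintf("%s=%.4f", names(object@perClass), object@perClass),
              collapse = ", "), "\n")
})

#' Risk-stratification rule
#'
#' Threshold rule assigning each prostate-cancer case a low/medium/high
#' risk group from Gleason score, serum PSA (ng/mL) and clinical T-stage,
#' evaluated with precedence high > medium > low so exactly one group fires.
#' Defaults follow the D'Amico-style convention: high if Gleason >= 8 or
#' PSA > 20 or stage >= T2c; else medium if Gleason == 7 or 10 <= PSA <= 20
#' or stage == T2b; else low.
#'
#' @slot gleasonHigh Gleason score at or above which a case is high risk.
#' @slot psaHigh PSA strictly above which a case is high risk.
#' @slot stageHigh clinical stage at or above which a case is high risk.
#' @slot gleasonMedium Gleason score that makes a non-high case medium.
#' @slot psaMediumLow,psaMediumHigh inclusive PSA band for medium risk.
#' @slot stageMedium clinical stage that makes a non-high case medium.
#' @seealso [assignRisk()], [stratifyCohort()]
#' @export
setClass("RiskRule", representation(
  gleasonHigh = "numeric",
  psaHigh = "numeric",
  stageHigh = "character",
  gleasonMedium = "numeric",
  psaMediumLow = "numeric",
  psaMediumHigh = "numeric",
  stageMedium = "character"
))

setValidity("RiskRule", function(object) {
  msg <- character()
  if (!object@stageHigh %in% clinicalStages())
    msg <- c(msg, "stageHigh must be a valid clinical stage")
  if (!object@stageMedium %in% clinicalStages())
    msg <- c(msg, "stageMedium must be a valid clinical stage")
  if (object@psaMediumLow > object@psaMediumHigh)
    msg <- c(msg, "psaMediumLow must be <= psaMediumHigh")
  if (object@gleasonMedium >= object@gleasonHigh)
    msg <- c(msg, "gleasonMedium must be below gleasonHigh")
  if (length(msg)) msg else TRUE
})

#' Default D'Amico-style risk rule
#'
#' @param gleasonHigh,psaHigh,stageHigh high-risk thresholds.
#' @param gleasonMedium,psaMediumLow,psaMediumHigh,stageMedium medium-risk
#'   thresholds.
#' @return A [RiskRule-class].
#' @examples
#' defaultRiskRule()
#' @export
defaultRiskRule <- function(gleasonHigh = 8, psaHigh = 20,
                            stageHigh = "T2c", gleasonMedium = 7,
                            psaMediumLow = 10, psaMediumHigh = 20,
                            stageMedium = "T2b") {
  new("RiskRule", gleasonHigh = gleasonHigh, psaHigh = psaHigh,
      stageHigh = stageHigh, gleasonMedium = gleasonMedium,
      psaMediumLow = psaMediumLow, psaMediumHigh = psaMediumHigh,
      stageMedium = stageMedium)
}

setMethod("show", "RiskRule", function(object) {
  cat("RiskRule (precedence high > medium > low)\n")
  cat(sprintf("  high:   Gleason >= %g OR PSA > %g OR stage >= %s\n",
              object@gleasonHigh, object@psaHigh, object@stageHigh))
  cat(sprintf("  medium: Gleason == %g OR %g <= PSA <= %g OR stage == %s\n",
              object@gleasonMedium, object@psaMediumLow,
              object@psaMediumHigh, object@stageMedium))
  cat("  low:    otherwise\n")
})

#' Pearson chi-square test result
#'
#' @slot statistic Pearson chi-square statistic.
#' @slot df degrees of freedom, (r - 1)(k - 1).
#' @slot pValue upper-tail p-value.
#' @slot expected matrix of expected counts under independence.
#' @export
setClass("ChiSquareResult", representation(
  statistic = "numeric",
  df = "numeric",
  pValue = "numeric",
  expected = "matrix"
))

setMethod("show", "ChiSquareResult", function(object) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.4g\n",
              object@statistic, as.integer(object@df), object@pValue))
})
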