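# Synthetic T2WI-like prostate phantoms: an elliptical gland (central +
# marginal zones) in surrounding tissue, with optional dark lesions and
# paired clinical case records. Stands in for a patient cohort so the whole
# segmentation pipeline is testable without data.

#' Clinical T-stage levels in ascending order
#'
#' @return Character vector `T1 < T2a < T2b < T2c < T3 < T4`.
#' @examples
#' clinicalStages()
#' @export
clinicalStages <- function() c("T1", "T2a", "T2b", "T2c", "T3", "T4")

# Rasterize the two concentric gland ellipses; returns the label mask
# (0 surrounding, 1 central, 2 marginal). Purely deterministic.
phantomGeometry <- function(params) {
  h <- params@imageHeight; w <- params@imageWidth
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # semi-axes in pixels: transverse along columns, antero-posterior along rows
  a <- params@glandTransverseAxis / 2 / params@pixelSpacing
  b <- params@glandAPAxis / 2 / params@pixelSpacing
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  e <- ((cols - cx) / a)^2 + ((rows - cy) / b)^2
  f <- params@centralFraction
  mask <- matrix(0L, h, w)
  mask[e <= 1] <- 2L        # whole gland, provisionally marginal
  mask[e <= f^2] <- 1L      # concentric central zone
  mask
}

noiselessImage <- function(mask, params) {
  m <- params@intensityMeans
  img <- matrix(m[["surrounding"]], nrow(mask), ncol(mask))
  img[mask == 1L] <- m[["central"]]
  img[mask == 2L] <- m[["marginal"]]
  img
}

#' Generate one synthetic prostate slice
#'
#' Produces an intensity image and its ground-truth three-class label mask
#' (0 = surrounding tissue, 1 = central gland, 2 = marginal gland). The
#' image is the class-mean intensity map plus zero-mean Gaussian noise of
#' standard deviation `noiseSD`. Identical `(params, seed)` pairs give
#' bit-identical output; the caller's RNG stream is left untouched.
#'
#' @param params a [PhantomParams-class].
#' @param seed integer seed for the noise field.
#' @return A list with elements `image` (numeric matrix) and `mask`
#'   (integer matrix with values in \{0, 1, 2\}).
#' @examples
#' ph <- generatePhantom(PhantomParams(), seed = 1)
#' table(ph$mask)
#' @export
generatePhantom <- function(params, seed) {
  validObject(params)
  mask <- phantomGeometry(params)
  img <- noiselessImage(mask, params)
  if (params@noiseSD > 0) {
    noise <- withSeed(seed, matrix(stats::rnorm(length(img), 0,
                                                params@noiseSD),
                                   nrow(img), ncol(img)))
    img <- img + noise
  }
  list(image = img, mask = mask)
}

#' Insert a low-signal lesion into a phantom
#'
#' Sets pixels of the lesion disc that lie inside the gland (mask classes
#' 1 or 2) to `lesionIntensity`. Lesions emulate the dark foci of prostate
#' cancer on T2WI, so `lesionIntensity` should sit below the gland class
#' means. The tissue-class mask is not modified: the lesion remains part of
#' its gland zone anatomically, and the returned `lesionMask` records which
#' pixels it covers. The operation is deterministic; apply it to a
#' noiseless image and add noise afterwards.
#'
#' @param image numeric intensity matrix.
#' @param mask integer label mask matching `image`.
#' @param center length-2 integer `(row, col)` of the lesion center; must
#'   lie inside the gland.
#' @param radius disc radius in pixels, > 0.
#' @param lesionIntensity intensity assigned to lesion pixels.
#' @return A list with elements `image` (modified copy) and `lesionMask`
#'   (logical matrix).
#' @examples
#' ph <- generatePhantom(PhantomParams(noiseSD = 0), seed = 1)
#' les <- insertLesion(ph$image, ph$mask, center = c(32, 32), radius = 4,
#'                     lesionIntensity = 70)
#' sum(les$lesionMask)
#' @export
insertLesion <- function(image, mask, center, radius, lesionIntensity) {
  stopIfNot2D(image, "image"); stopIfNot2D(mask, "mask")
  if (!all(dim(image) == dim(mask)))
    stop("image and mask dimensions differ", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  r0 <- center[1]; c0 <- center[2]
  if (r0 < 1 || r0 > nrow(mask) || c0 < 1 || c0 > ncol(mask) ||
      mask[r0, c0] == 0L)
    stop("lesion center must lie inside the gland", call. = FALSE)
  rows <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cols <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  inDisc <- (rows - r0)^2 + (cols - c0)^2 <= radius^2
  lesionMask <- inDisc & mask > 0L
  image[lesionMask] <- lesionIntensity
  list(image = image, lesionMask = lesionMask)
}

# Split a Gleason score into a (primary, secondary) pattern pair, each in
# 1..5. Ambiguous sums pick the ordering at random from the supplied stream.
gleasonSplit <- function(score) {
  lo <- max(1L, score - 5L); hi <- min(5L, score - 1L)
  primary <- if (hi > lo) sample(seq.int(lo, hi), 1L) else lo
  c(primary = primary, secondary = score - primary)
}

#' Sampling model for synthetic clinical case records
#'
#' The categorical and log-normal distributions from which
#' [sampleCaseRecord()] draws. Cancer cases: Gleason score over
#' \{6, 7, 8, 9, 10\} with probabilities (0.35, 0.40, 0.15, 0.08, 0.02),
#' PSA log-normal with median 12 ng/mL and log-sd 0.6, clinical stage over
#' the six T-stages with probabilities (0.20, 0.20, 0.25, 0.15, 0.15,
#' 0.05). Hyperplasia cases: Gleason floor (1 + 1 = 2) and PSA log-normal
#' with median 4 ng/mL and log-sd 0.5, stage T1.
#'
#' @return A list with components `gleasonScores`, `gleasonProbs`,
#'   `stageProbs`, `psaCancer`, `psaBenign`.
#' @examples
#' caseSamplingModel()$gleasonProbs
#' @export
caseSamplingModel <- function() {
  list(
    gleasonScores = 6:10,
    gleasonProbs = c(0.35, 0.40, 0.15, 0.08, 0.02),
    stageProbs = c(T1 = 0.20, T2a = 0.20, T2b = 0.25, T2c = 0.15,
                   T3 = 0.15, T4 = 0.05),
    psaCancer = c(meanlog = log(12), sdlog = 0.6),
    psaBenign = c(meanlog = log(4), sdlog = 0.5)
  )
}

#' Sample one clinical case record
#'
#' Draws Gleason primary/secondary patterns, PSA and clinical T-stage from
#' [caseSamplingModel()]. Hyperplasia cases carry the benign regime
#' (Gleason floor 2, low PSA, stage T1) and an unset risk group; risk
#' groups are only ever assigned to cancer cases.
#'
#' @param trueClass `"cancer"` or `"hyperplasia"`.
#' @param seed integer seed.
#' @param caseId case identifier string.
#' @return One-row data.frame with columns `case_id`, `true_class`,
#'   `gleason_primary`, `gleason_secondary`, `gleason_score`, `psa`,
#'   `clinical_stage`, `risk_group` (NA until assigned).
#' @examples
#' sampleCaseRecord("cancer", seed = 7)
#' @export
sampleCaseRecord <- function(trueClass = c("cancer", "hyperplasia"), seed,
                             caseId = "case001") {
  trueClass <- match.arg(trueClass)
  model <- caseSamplingModel()
  withSeed(seed, {
    if (trueClass == "cancer") {
      score <- sample(model$gleasonScores, 1L, prob = model$gleasonProbs)
      pat <- gleasonSplit(as.integer(score))
      psa <- stats::rlnorm(1L, model$psaCancer[["meanlog"]],
                           model$psaCancer[["sdlog"]])
      stage <- sample(names(model$stageProbs), 1L, prob = model$stageProbs)
    } else {
      pat <- c(primary = 1L, secondary = 1L)
      psa <- stats::rlnorm(1L, model$psaBenign[["meanlog"]],
                           model$psaBenign[["sdlog"]])
      stage <- "T1"
    }
    data.frame(case_id = caseId, true_class = trueClass,
               gleason_primary = as.integer(pat[["primary"]]),
               gleason_secondary = as.integer(pat[["secondary"]]),
               gleason_score = as.integer(sum(pat)),
               psa = psa, clinical_stage = stage,
               risk_group = NA_character_,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic cohort of phantom slices with case records
#'
#' Builds `nCancer + nHyperplasia` cases. Each case gets its own seed
#' derived from the master seed, a phantom slice, and a clinical record.
#' Cancer cases receive a low-signal lesion with probability
#' `params@lesionProbabilityGivenCancer`: the lesion center is a uniformly
#' drawn gland pixel and its radius uniform over `params@lesionRadiusRange`;
#' the lesion is stamped into the noiseless image before noise is added, so
#' it reads as a dark focus of the configured lesion intensity.
#'
#' @param nCancer,nHyperplasia non-negative case counts (defaults match a
#'   89-patient cohort split 39 cancer / 50 hyperplasia).
#' @param params a [PhantomParams-class].
#' @param seed master seed.
#' @return A list with elements `images`, `masks`, `lesionMasks` (lists of
#'   matrices; `lesionMasks[[i]]` is NULL when case i has no lesion) and
#'   `records` (data.frame, one row per case, with a logical `has_lesion`
#'   column appended).
#' @examples
#' coh <- generateCohort(3, 4, PhantomParams(), seed = 1)
#' table(coh$records$true_class)
#' @export
generateCohort <- function(nCancer = 39L, nHyperplasia = 50L,
                           params = PhantomParams(), seed = 1L) {
  validObject(params)
  if (nCancer < 0L || nHyperplasia < 0L)
    stop("case counts must be >= 0", call. = FALSE)
  n <- nCancer + nHyperplasia
  classes <- rep(c("cancer", "hyperplasia"), c(nCancer, nHyperplasia))
  geom <- phantomGeometry(params)
  base <- noiselessImage(geom, params)
  glandIdx <- which(geom > 0L)
  images <- masks <- lesionMasks <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    caseId <- sprintf("case%03d", i)
    caseSeed <- deriveSeed(seed, caseId)
    rec <- sampleCaseRecord(classes[i], seed = deriveSeed(caseSeed, "record"),
                            caseId = caseId)
    img <- base
    lesion <- NULL
    if (classes[i] == "cancer") {
      hasLesion <- withSeed(deriveSeed(caseSeed, "lesion"), {
        if (stats::runif(1) < params@lesionProbabilityGivenCancer) {
          ctr <- arrayInd(sample(glandIdx, 1L), dim(geom))
          rad <- stats::runif(1, params@lesionRadiusRange[1],
                              params@lesionRadiusRange[2])
          list(center = as.integer(ctr), radius = rad)
        } else NULL
      })
      if (!is.null(hasLesion)) {
        ins <- insertLesion(img, geom, hasLesion$center, hasLesion$radius,
                            params@intensityMeans[["lesion"]])
        img <- ins$image
        lesion <- ins$lesionMask
      }
    }
    if (params@noiseSD > 0)
      img <- img + withSeed(deriveSeed(caseSeed, "noise"),
                            matrix(stats::rnorm(length(img), 0,
                                                params@noiseSD),
                                   nrow(img), ncol(img)))
    rec$has_lesion <- !is.null(lesion)
    images[[i]] <- img
    masks[[i]] <- geom
    lesionMasks[i] <- list(lesion)  # keep NULL entries in place
    records[[i]] <- rec
  }
  list(images = images, masks = masks, lesionMasks = lesionMasks,
       records = do.call(rbind, records))
}
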