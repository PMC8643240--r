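# End-to-end pipeline: simulate -> train -> segment -> evaluate ->
# stratify -> concordance, with a run manifest next to every output set.
# All stage seeds derive from one master seed, so each stage is
# independently reproducible and a full rerun is byte-identical.

writeManifest <- function(path, fields) {
  fields$package <- "ProstateSegNet"
  fields$version <- as.character(utils::packageVersion("ProstateSegNet"))
  writeLines(yaml::as.yaml(fields), path)
  invisible(path)
}

phantomParamsToList <- function(p) {
  list(imageHeight = p@imageHeight, imageWidth = p@imageWidth,
       pixelSpacing = p@pixelSpacing,
       glandTransverseAxis = p@glandTransverseAxis,
       glandAPAxis = p@glandAPAxis, centralFraction = p@centralFraction,
       intensityMeans = as.list(p@intensityMeans), noiseSD = p@noiseSD,
       lesionProbabilityGivenCancer = p@lesionProbabilityGivenCancer,
       lesionRadiusRange = p@lesionRadiusRange)
}

networkConfigToList <- function(cfg) {
  list(encoderChannels = cfg@encoderChannels,
       decoderChannels = cfg@decoderChannels,
       kernelSize = cfg@kernelSize, poolWindow = cfg@poolWindow,
       nClasses = cfg@nClasses, inputSize = cfg@inputSize,
       learningRate = cfg@learningRate, epochs = cfg@epochs,
       batchSize = cfg@batchSize, optimizer = cfg@optimizer,
       seed = cfg@seed, bnEpsilon = cfg@bnEpsilon,
       bnMomentum = cfg@bnMomentum, classWeights = cfg@classWeights)
}

#' Build configuration objects from a YAML/JSON-style list or file
#'
#' The config file mirrors the constructor arguments field-for-field under
#' the top-level keys `phantom` and `network`; unknown keys are rejected.
#'
#' @param x path to a YAML file, or an already-parsed list.
#' @return A list with elements `phantom` ([PhantomParams-class]) and
#'   `network` ([NetworkConfig-class]); missing sections give defaults.
#' @examples
#' cfg <- loadRunConfig(list(network = list(epochs = 2)))
#' cfg$network@epochs
#' @export
loadRunConfig <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("no such config file: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  if (is.null(x)) x <- list()
  bad <- setdiff(names(x), c("phantom", "network"))
  if (length(bad))
    stop("unknown config sections: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ph <- x$phantom
  if (!is.null(ph$intensityMeans)) ph$intensityMeans <-
      unlist(ph$intensityMeans)
  phantom <- do.call(PhantomParams, if (is.null(ph)) list() else ph)
  net <- x$network
  network <- do.call(NetworkConfig, if (is.null(net)) list() else net)
  list(phantom = phantom, network = network)
}

#' Simulate a cohort to disk
#'
#' Writes per-case PNG images and masks, the case-record CSV and a run
#' manifest under `outDir`.
#'
#' @param outDir output directory (created if missing).
#' @param nCancer,nHyperplasia case counts.
#' @param params a [PhantomParams-class].
#' @param seed master seed.
#' @return The cohort list from [generateCohort()], invisibly.
#' @export
simulateCohort <- function(outDir, nCancer = 39L, nHyperplasia = 50L,
                           params = PhantomParams(), seed = 1L) {
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "masks"), showWarnings = FALSE)
  coh <- generateCohort(nCancer, nHyperplasia, params, seed)
  for (i in seq_along(coh$images)) {
    id <- coh$records$case_id[i]
    saveImage(coh$images[[i]], file.path(outDir, "images",
                                         paste0(id, ".png")))
    saveMask(coh$masks[[i]], file.path(outDir, "masks",
                                       paste0(id, ".png")))
  }
  writeCaseRecords(coh$records, file.path(outDir, "records.csv"))
  writeManifest(file.path(outDir, "manifest.yaml"),
                list(stage = "simulate", seed = seed,
                     nCancer = nCancer, nHyperplasia = nHyperplasia,
                     phantom = phantomParamsToList(params)))
  invisible(coh)
}

# Gland estimate without the CNN: plain intensity thresholding, the
# "before processing" arm of the demo comparison. The threshold sits
# between the surrounding and central-gland means.
thresholdGland <- function(image, cutoff = 115) image > cutoff

#' Run the full demonstration pipeline
#'
#' Simulates a cohort, trains the PSSNET on its images, segments every
#' slice, evaluates foreground Dice/Hausdorff per case, calls
#' cancer/hyperplasia with the lesion-presence heuristic on both a plain
#' intensity-threshold gland estimate ("before processing") and the CNN
#' segmentation ("after processing"), stratifies the detected true-cancer
#' cases, and writes `metrics.csv`, `detections.csv`, `strata.csv`,
#' `report.csv` and `manifest.yaml` under `outDir`. Every stage seed
#' derives from `seed`, so a rerun with the same arguments is
#' byte-identical.
#'
#' @param outDir output directory.
#' @param seed master seed.
#' @param nCancer,nHyperplasia cohort composition (defaults 39/50).
#' @param params a [PhantomParams-class].
#' @param config a [NetworkConfig-class]; its `seed` is overridden by one
#'   derived from the master seed.
#' @return Invisibly, a list with the trained model, per-case metrics,
#'   detection table, strata table and concordance report.
#' @export
runDemo <- function(outDir, seed = 1L, nCancer = 39L, nHyperplasia = 50L,
                    params = PhantomParams(), config = NetworkConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  coh <- generateCohort(nCancer, nHyperplasia, params,
                        deriveSeed(seed, "simulate"))
  config@seed <- deriveSeed(seed, "train")
  model <- trainPSSNet(coh$images, coh$masks, config)

  n <- length(coh$images)
  segs <- lapply(coh$images, function(img) segmentImage(model, img))
  metrics <- do.call(rbind, lapply(seq_len(n), function(i) {
    sm <- evaluateSegmentation(segs[[i]]$mask, coh$masks[[i]])
    data.frame(case_id = coh$records$case_id[i], dsc = sm@dsc,
               hd = sm@hd, hd_forward = sm@hdForward,
               hd_backward = sm@hdBackward, stringsAsFactors = FALSE)
  }))

  cutoff <- mean(params@intensityMeans[c("lesion", "central")])
  glandThresh <- mean(params@intensityMeans[c("surrounding", "central")])
  callPre <- vapply(seq_len(n), function(i)
    callCancerFromSegmentation(coh$images[[i]],
                               thresholdGland(coh$images[[i]], glandThresh),
                               intensityCutoff = cutoff), logical(1))
  callPost <- vapply(seq_len(n), function(i)
    callCancerFromSegmentation(coh$images[[i]], segs[[i]]$mask,
                               intensityCutoff = cutoff), logical(1))
  isCancer <- coh$records$true_class == "cancer"
  detections <- data.frame(
    method = c("pathology", "mri_pre", "mri_post"),
    n_cancer = c(sum(isCancer), sum(callPre), sum(callPost)),
    n_hyperplasia = c(sum(!isCancer), sum(!callPre), sum(!callPost)),
    stringsAsFactors = FALSE)

  # Risk grading applies to confirmed cancers: the pathology row uses all
  # true cancer cases, the MRI rows the true cancers each method detected.
  strata <- do.call(rbind, lapply(
    list(pathology = isCancer, mri_pre = isCancer & callPre,
         mri_post = isCancer & callPost),
    function(sel) as.data.frame(t(stratifyCohort(coh$records[sel, ])))))
  strata <- cbind(method = rownames(strata), strata,
                  stringsAsFactors = FALSE)
  rownames(strata) <- NULL

  report <- concordanceReport(detections, strata)

  utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(detections, file.path(outDir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(strata, file.path(outDir, "strata.csv"),
                   row.names = FALSE)
  utils::write.csv(report, file.path(outDir, "report.csv"),
                   row.names = FALSE)
  writeManifest(file.path(outDir, "manifest.yaml"),
                list(stage = "demo", seed = seed, nCancer = nCancer,
                     nHyperplasia = nHyperplasia,
                     phantom = phantomParamsToList(params),
                     network = networkConfigToList(config)))
  invisible(list(model = model, metrics = metrics,
                 detections = detections, strata = strata,
                 report = report))
}

#' Dispatch a pipeline subcommand
#'
#' Thin programmatic entry point behind the command-line script:
#' `simulate`, `train`, `segment`, `evaluate`, `stratify`, `concordance`
#' or `demo`. Validation failures raise the originating module's error;
#' the return value is 0 on success (for shell exit-status use).
#'
#' @param subcommand one of the subcommand names.
#' @param args named list of arguments for the subcommand (paths, counts,
#'   `seed`, `config` file path).
#' @return Integer exit status 0, invisibly.
#' @export
runPipeline <- function(subcommand = c("simulate", "train", "segment",
                                       "evaluate", "stratify",
                                       "concordance", "demo"),
                        args = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- loadRunConfig(args$config)
  seed <- if (is.null(args$seed)) 1L else as.integer(args$seed)
  switch(subcommand,
    simulate = simulateCohort(args$out,
                              nCancer = args$nCancer %||% 39L,
                              nHyperplasia = args$nHyperplasia %||% 50L,
                              params = cfg$phantom, seed = seed),
    train = {
      imgFiles <- sort(list.files(file.path(args$data, "images"),
                                  full.names = TRUE))
      mskFiles <- sort(list.files(file.path(args$data, "masks"),
                                  full.names = TRUE))
      if (!length(imgFiles)) stop("no images under ", args$data,
                                  call. = FALSE)
      net <- cfg$network
      net@seed <- seed
      model <- trainPSSNet(lapply(imgFiles, loadImage),
                           lapply(mskFiles, loadMask), net)
      saveModel(model, args$out)
      writeManifest(paste0(args$out, ".manifest.yaml"),
                    list(stage = "train", seed = seed,
                         network = networkConfigToList(net)))
    },
    segment = {
      model <- loadModel(args$model)
      seg <- segmentImage(model, loadImage(args$image))
      saveMask(seg$mask, args$out)
    },
    evaluate = {
      sm <- evaluateSegmentation(loadMask(args$pred), loadMask(args$ref),
                                 mode = args$mode %||% "foreground")
      utils::write.csv(
        data.frame(case_id = args$caseId %||% basename(args$pred),
                   dsc = sm@dsc, hd = sm@hd, hd_forward = sm@hdForward,
                   hd_backward = sm@hdBackward),
        args$out, row.names = FALSE)
    },
    stratify = {
      rec <- readCaseRecords(args$records)
      rec <- rec[rec$true_class == "cancer", ]
      counts <- stratifyCohort(rec)
      utils::write.csv(data.frame(risk_group = names(counts),
                                  n = as.integer(counts)),
                       args$out, row.names = FALSE)
    },
    concordance = {
      det <- utils::read.csv(args$detections, stringsAsFactors = FALSE)
      str <- if (!is.null(args$strata))
        utils::read.csv(args$strata, stringsAsFactors = FALSE) else NULL
      utils::write.csv(concordanceReport(det, str), args$out,
                       row.names = FALSE)
    },
    demo = runDemo(args$out, seed = seed,
                   nCancer = args$nCancer %||% 39L,
                   nHyperplasia = args$nHyperplasia %||% 50L,
                   params = cfg$phantom, config = cfg$network))
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
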