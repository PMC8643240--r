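# Diagnostic-concordance statistics on detection-count tables: positive
# rates, Pearson chi-square tests and method-vs-pathology comparison
# reports.

#' Positive rate of a detection method
#'
#' `100 * nCancer / (nCancer + nHyperplasia)`, rounded half-up to the
#' nearest integer percent (the rounding rule consistent with reporting
#' 43.82 as 44, 33.71 as 34 and 41.57 as 42).
#'
#' @param nCancer,nHyperplasia non-negative case counts, not both zero.
#' @param exact if TRUE, return the unrounded percentage.
#' @return Percentage (numeric scalar).
#' @examples
#' positiveRate(39, 50)  # 44
#' @export
positiveRate <- function(nCancer, nHyperplasia, exact = FALSE) {
  if (nCancer < 0 || nHyperplasia < 0)
    stop("counts must be >= 0", call. = FALSE)
  total <- nCancer + nHyperplasia
  if (total == 0) stop("total case count is zero", call. = FALSE)
  pct <- 100 * nCancer / total
  if (exact) pct else roundHalfUp(pct)
}

#' Pearson chi-square test on a contingency table
#'
#' The Pearson statistic `sum((O - E)^2 / E)` with expected counts from
#' the row/column margins and `df = (r - 1)(k - 1)`. No continuity
#' correction is applied by default (all expected counts in the intended
#' tables are well above 5); set `correct = TRUE` for the Yates-corrected
#' 2x2 variant.
#'
#' @param counts numeric matrix of non-negative counts (r x k, both >= 2).
#' @param correct logical, Yates continuity correction for 2x2 tables.
#' @return A [ChiSquareResult-class].
#' @examples
#' chiSquare(rbind(c(10, 0), c(0, 10)))
#' @export
chiSquare <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin: expected counts undefined",
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  new("ChiSquareResult",
      statistic = unname(ct$statistic),
      df = unname(ct$parameter),
      pValue = unname(ct$p.value),
      expected = ct$expected)
}

#' Transcribed detection-count and risk-stratum tables
#'
#' Reads the bundled CSV transcriptions of the study's detection counts
#' (pathological biopsy vs MRI before/after CNN processing, 89 cases) and
#' risk-stratum counts per method.
#'
#' @return `referenceDetectionTable()`: data.frame with columns `method`,
#'   `n_cancer`, `n_hyperplasia`. `referenceStrataTable()`: data.frame
#'   with columns `method`, `low`, `medium`, `high`.
#' @examples
#' referenceDetectionTable()
#' @export
referenceDetectionTable <- function() {
  utils::read.csv(system.file("extdata", "table2.csv",
                              package = "ProstateSegNet"),
                  stringsAsFactors = FALSE)
}

#' @rdname referenceDetectionTable
#' @export
referenceStrataTable <- function() {
  utils::read.csv(system.file("extdata", "table3.csv",
                              package = "ProstateSegNet"),
                  stringsAsFactors = FALSE)
}

#' Concordance report of detection methods against pathology
#'
#' For each detection method, computes its positive rate, the absolute
#' difference in percentage points from the pathology rate, and the
#' Pearson chi-square test of its 2x2 cancer/hyperplasia counts against
#' pathology's. When a strata table is supplied, per-stratum count
#' differences from the pathology row are appended.
#'
#' @param detections data.frame with columns `method`, `n_cancer`,
#'   `n_hyperplasia`; one row must have `method == "pathology"`.
#' @param strata optional data.frame with columns `method`, `low`,
#'   `medium`, `high` including a pathology row.
#' @param correct passed to [chiSquare()].
#' @return A data.frame, one row per method, with columns `method`,
#'   `n_cancer`, `n_hyperplasia`, `positive_rate`, `rate_diff`,
#'   `chisq_stat`, `chisq_p` (NA for the pathology row itself) and, when
#'   `strata` is given, `low`, `medium`, `high`,
#'   `strata_abs_diff` (summed absolute per-stratum difference).
#' @examples
#' concordanceReport(referenceDetectionTable(), referenceStrataTable())
#' @export
concordanceReport <- function(detections, strata = NULL, correct = FALSE) {
  need <- c("method", "n_cancer", "n_hyperplasia")
  if (!all(need %in% names(detections)))
    stop("detections must have columns method, n_cancer, n_hyperplasia",
         call. = FALSE)
  pat <- detections[detections$method == "pathology", ]
  if (nrow(pat) != 1L)
    stop("detections must contain exactly one pathology row",
         call. = FALSE)
  patRate <- positiveRate(pat$n_cancer, pat$n_hyperplasia)
  rows <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    rate <- positiveRate(d$n_cancer, d$n_hyperplasia)
    if (d$method == "pathology") {
      stat <- p <- NA_real_
    } else {
      cs <- chiSquare(rbind(c(pat$n_cancer, pat$n_hyperplasia),
                            c(d$n_cancer, d$n_hyperplasia)),
                      correct = correct)
      stat <- cs@statistic; p <- cs@pValue
    }
    data.frame(method = d$method, n_cancer = d$n_cancer,
               n_hyperplasia = d$n_hyperplasia, positive_rate = rate,
               rate_diff = abs(rate - patRate), chisq_stat = stat,
               chisq_p = p, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (!is.null(strata)) {
    needS <- c("method", "low", "medium", "high")
    if (!all(needS %in% names(strata)))
      stop("strata must have columns method, low, medium, high",
           call. = FALSE)
    patS <- strata[strata$method == "pathology", ]
    if (nrow(patS) != 1L)
      stop("strata must contain exactly one pathology row", call. = FALSE)
    strata$strata_abs_diff <- abs(strata$low - patS$low) +
      abs(strata$medium - patS$medium) + abs(strata$high - patS$high)
    report <- merge(report, strata[, c(needS, "strata_abs_diff")],
                    by = "method", all.x = TRUE, sort = FALSE)
    report <- report[match(detections$method, report$method), ]
    rownames(report) <- NULL
  }
  report
}

#' Lesion-presence cancer call on a segmented slice
#'
#' Demo heuristic standing in for a radiologist's cancer/hyperplasia call:
#' a slice is called cancer when at least `minPixels` pixels inside the
#' predicted gland are darker than `intensityCutoff` (a low-signal focus).
#' The cutoff default is the midpoint between the default lesion and
#' central-gland intensities. This is a plumbing heuristic for end-to-end
#' demonstrations, not a validated diagnostic rule.
#'
#' @param image intensity matrix.
#' @param glandMask logical or integer mask marking the (predicted) gland.
#' @param intensityCutoff intensity below which a gland pixel counts as
#'   low-signal.
#' @param minPixels minimum low-signal pixel count for a cancer call.
#' @return Logical: cancer call.
#' @examples
#' ph <- generatePhantom(PhantomParams(), seed = 1)
#' callCancerFromSegmentation(ph$image, ph$mask)
#' @export
callCancerFromSegmentation <- function(image, glandMask,
                                       intensityCutoff = 105,
                                       minPixels = 5L) {
  stopIfNot2D(image, "image")
  gland <- if (is.logical(glandMask)) glandMask else glandMask > 0L
  if (!all(dim(gland) == dim(image)))
    stop("image and glandMask dimensions differ", call. = FALSE)
  sum(image[gland] < intensityCutoff) >= minPixels
}
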