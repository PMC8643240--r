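# Risk stratification of prostate-cancer cases from Gleason score, PSA and
# clinical T-stage, with cohort tabulation.

stageRank <- function(stage) {
  r <- match(stage, clinicalStages())
  if (anyNA(r)) stop("invalid clinical stage: ",
                     paste(stage[is.na(r)], collapse = ", "), call. = FALSE)
  r
}

#' Assign a risk group to a cancer case
#'
#' Applies a [RiskRule-class] with precedence high > medium > low, so every
#' valid (Gleason, PSA, stage) triple maps to exactly one group. Only
#' cancer cases are stratified; a hyperplasia record raises an error.
#'
#' @param record a one-row data.frame (or named list) with fields
#'   `true_class`, `gleason_score`, `psa`, `clinical_stage` — e.g. a row of
#'   [generateCohort()]'s records.
#' @param rule a [RiskRule-class]; defaults to [defaultRiskRule()].
#' @return `"low"`, `"medium"` or `"high"`.
#' @examples
#' rec <- list(true_class = "cancer", gleason_score = 7, psa = 15,
#'             clinical_stage = "T2b")
#' assignRisk(rec)
#' @export
assignRisk <- function(record, rule = defaultRiskRule()) {
  validObject(rule)
  if (!identical(as.character(record$true_class), "cancer"))
    stop("risk groups are assigned to cancer cases only", call. = FALSE)
  g <- as.numeric(record$gleason_score)
  psa <- as.numeric(record$psa)
  if (is.na(g) || g < 2 || g > 10)
    stop("gleason_score must lie in 2..10", call. = FALSE)
  if (is.na(psa) || psa < 0) stop("psa must be >= 0", call. = FALSE)
  st <- stageRank(as.character(record$clinical_stage))
  if (g >= rule@gleasonHigh || psa > rule@psaHigh ||
      st >= stageRank(rule@stageHigh)) return("high")
  if (g == rule@gleasonMedium ||
      (psa >= rule@psaMediumLow && psa <= rule@psaMediumHigh) ||
      st == stageRank(rule@stageMedium)) return("medium")
  "low"
}

#' Tabulate risk strata over a cancer cohort
#'
#' @param records data.frame of cancer case records (see [assignRisk()]).
#' @param rule a [RiskRule-class].
#' @return Named integer vector with entries `low`, `medium`, `high`
#'   summing to `nrow(records)`.
#' @examples
#' coh <- generateCohort(10, 0, PhantomParams(), seed = 3)
#' stratifyCohort(coh$records)
#' @export
stratifyCohort <- function(records, rule = defaultRiskRule()) {
  counts <- c(low = 0L, medium = 0L, high = 0L)
  if (is.null(records) || nrow(records) == 0L) return(counts)
  groups <- vapply(seq_len(nrow(records)),
                   function(i) assignRisk(records[i, ], rule), character(1))
  tab <- table(factor(groups, levels = names(counts)))
  counts[] <- as.integer(tab)
  counts
}

#' Histologic Gleason pattern reference
#'
#' Returns the five Gleason pattern (grade 1-5) descriptions as a
#' reference table, or a single pattern's description text. Purely
#' informational: risk assignment uses the numeric Gleason score.
#'
#' @param pattern optional integer in 1..5; when given, the description
#'   string for that pattern is returned.
#' @return A data.frame with columns `pattern` and `description`, or a
#'   character scalar when `pattern` is given.
#' @examples
#' substr(gleasonPatternReference(1), 1, 30)
#' @export
gleasonPatternReference <- function(pattern = NULL) {
  tab <- data.frame(
    pattern = 1:5,
    description = c(
      paste("Cancer tissue is extremely rare. Its borders are very clear,",
            "it grows expansively, and it hardly invades the matrix; the",
            "carcinomas are simple, usually round, and moderately sized and",
            "are packed together; the cytoplasm of cancer cells closely",
            "resembles that of benign epithelial cells."),
      paste("Cancer tissue is rare, which mostly occurs in the transitional",
            "area of the prostate. The tumor boundary is not very clear,",
            "and the carcinomas are separated by the stroma. They are",
            "simple, round, different in size, and irregular in shape and",
            "are loosely arranged together."),
      paste("Cancer tissue is the most common, which mostly occurs in the",
            "peripheral area of the prostate. Its most important feature is",
            "invasive growth, the carcinomas are of different sizes and",
            "shapes, nucleoli are large and red, and the cytoplasm is",
            "mostly alkaline staining."),
      paste("The cancer tissue is poorly differentiated and grows",
            "infiltrating; the carcinomas are irregularly fused to form",
            "tiny papillary or sieve-shaped, large and red nucleoli; the",
            "cytoplasm can be alkaline or gray."),
      paste("The cancer tissue is very poorly differentiated. The border",
            "can be regularly round or irregular, accompanied by invasive",
            "growth; the growth form is sheet-like single cell type or",
            "acne-like carcinoma type, accompanied by necrosis; cancer",
            "cells have large nuclei and large and red nucleoli;",
            "cytoplasmic staining may vary.")),
    stringsAsFactors = FALSE)
  if (is.null(pattern)) return(tab)
  pattern <- as.integer(pattern)
  if (length(pattern) != 1L || is.na(pattern) || pattern < 1L ||
      pattern > 5L)
    stop("pattern must be an integer in 1..5", call. = FALSE)
  tab$description[pattern]
}
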