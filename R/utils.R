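# Internal helpers shared across modules.

#' Run code under a seed without disturbing the global RNG state
#'
#' Saves and restores `.Random.seed` around a `set.seed()` call so that no
#' package operation leaks into (or depends on) the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Stable polynomial string hash of `(seed, tag)` modulo 2^31 - 1, so every
#' pipeline stage and every cohort case is independently reproducible from
#' the master seed.
#'
#' @param seed master seed (integer).
#' @param tag character or numeric stage label.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @examples
#' deriveSeed(42, "train")
#' @export
deriveSeed <- function(seed, tag) {
  m <- 2147483647
  h <- as.double(as.integer(seed) %% m)
  for (k in utf8ToInt(paste(as.character(tag), collapse = "/")))
    h <- (h * 31 + k) %% m
  as.integer(h %% (m - 2) + 1)
}

# Round half away from zero (printed percentages use half-up, not the
# IEEE banker's rounding of base::round).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopIfNot2D <- function(x, what) {
  if (!is.matrix(x)) stop(what, " must be a 2D matrix", call. = FALSE)
  invisible(x)
}
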