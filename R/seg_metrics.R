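# Segmentation-quality metrics: Dice similarity coefficient on filled
# pixel regions and directed/symmetric Hausdorff distance on boundary
# pixel sets.

# Accept pixel sets as n x 2 (row, col) matrices or logical masks.
asPixelSet <- function(x, what = "pixel set") {
  if (is.logical(x) && is.matrix(x)) x <- which(x, arr.ind = TRUE)
  if (!is.matrix(x) || ncol(x) != 2L)
    stop(what, " must be a logical mask or an n x 2 coordinate matrix",
         call. = FALSE)
  unique(x)
}

#' Dice similarity coefficient
#'
#' Overlap agreement `2|M ∩ N| / (|M| + |N|)` between a reference
#' pixel region M and a predicted region N, in \[0, 1\]: 1 iff the
#' non-empty sets coincide, 0 iff they are disjoint. Two empty sets leave
#' the coefficient undefined (0/0) and raise an error.
#'
#' @param M,N pixel sets: logical masks or `n x 2` (row, col) coordinate
#'   matrices. Duplicate coordinates are ignored.
#' @return The coefficient, a scalar in \[0, 1\].
#' @examples
#' dice(rbind(c(1, 1), c(1, 2), c(2, 1)),
#'      rbind(c(1, 1), c(1, 2), c(3, 3), c(4, 4), c(5, 5)))
#' @export
dice <- function(M, N) {
  M <- asPixelSet(M, "M"); N <- asPixelSet(N, "N")
  if (nrow(M) == 0L && nrow(N) == 0L)
    stop("Dice coefficient undefined for two empty sets", call. = FALSE)
  keysM <- paste(M[, 1], M[, 2])
  keysN <- paste(N[, 1], N[, 2])
  2 * sum(keysM %in% keysN) / (length(keysM) + length(keysN))
}

#' Directed Hausdorff distance
#'
#' `h(A, B) = max over a in A of min over b in B of ||a - b||` (Euclidean):
#' how far the worst-placed point of A lies from B. Asymmetric in general.
#'
#' @param A,B non-empty pixel sets (logical masks or coordinate matrices).
#' @return The directed distance in pixel units.
#' @examples
#' directedHausdorff(rbind(c(0, 0)), rbind(c(3, 4)))  # 5
#' @export
directedHausdorff <- function(A, B) {
  A <- asPixelSet(A, "A"); B <- asPixelSet(B, "B")
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("Hausdorff distance requires non-empty sets", call. = FALSE)
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(max(apply(d2, 1L, min)))
}

#' Symmetric Hausdorff distance
#'
#' `HD(M, N) = max(h(M, N), h(N, M))`: the worst-case mismatch between two
#' point sets. Zero iff the sets are equal.
#'
#' @inheritParams directedHausdorff
#' @param M,N non-empty pixel sets.
#' @return The symmetric distance in pixel units.
#' @examples
#' hausdorff(rbind(c(0, 0)), rbind(c(0, 0), c(10, 0)))  # 10
#' @export
hausdorff <- function(M, N) {
  max(directedHausdorff(M, N), directedHausdorff(N, M))
}

#' Boundary pixels of a foreground mask
#'
#' A foreground pixel is a boundary pixel when at least one of its
#' 4-neighbors is background; pixels on the image edge count their
#' out-of-image neighbors as background.
#'
#' @param fg logical foreground matrix.
#' @return Logical matrix marking the boundary.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
#' sum(boundaryPixels(m))  # the 8-pixel ring
#' @export
boundaryPixels <- function(fg) {
  stopIfNot2D(fg, "fg")
  h <- nrow(fg); w <- ncol(fg)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- fg
  inner <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  fg & !inner
}

#' Evaluate a predicted segmentation against a reference
#'
#' In `"foreground"` mode the gland (classes 1 and 2 pooled) of prediction
#' and reference are compared: Dice on the filled regions and Hausdorff
#' distance on their boundary pixel sets. In `"per_class"` mode a Dice
#' coefficient is computed for each class (plus the macro average in the
#' `perClass` slot under `"macro"`), with foreground Dice/HD still filling
#' the main slots.
#'
#' @param pred,ref integer label masks of identical dimensions (0
#'   surrounding, 1 central, 2 marginal).
#' @param mode `"foreground"` or `"per_class"`.
#' @param pixelSpacing optional mm/pixel; when supplied, Hausdorff
#'   distances are reported in mm.
#' @return A [SegMetrics-class].
#' @examples
#' ph <- generatePhantom(PhantomParams(), seed = 1)
#' evaluateSegmentation(ph$mask, ph$mask)
#' @export
evaluateSegmentation <- function(pred, ref,
                                 mode = c("foreground", "per_class"),
                                 pixelSpacing = NULL) {
  mode <- match.arg(mode)
  stopIfNot2D(pred, "pred"); stopIfNot2D(ref, "ref")
  if (!all(dim(pred) == dim(ref)))
    stop("pred and ref dimensions differ", call. = FALSE)
  refFg <- ref > 0L
  predFg <- pred > 0L
  if (!any(refFg))
    stop("reference foreground is empty", call. = FALSE)
  dsc <- if (any(predFg)) dice(refFg, predFg) else 0
  if (any(predFg)) {
    bM <- boundaryPixels(refFg)
    bN <- boundaryPixels(predFg)
    hf <- directedHausdorff(bM, bN)
    hb <- directedHausdorff(bN, bM)
  } else {
    hf <- hb <- Inf
  }
  units <- "px"
  if (!is.null(pixelSpacing)) {
    hf <- hf * pixelSpacing; hb <- hb * pixelSpacing
    units <- "mm"
  }
  perClass <- numeric()
  if (mode == "per_class") {
    classes <- sort(unique(c(as.vector(ref), as.vector(pred))))
    perClass <- vapply(classes, function(cl) {
      m <- ref == cl; n <- pred == cl
      if (!any(m) && !any(n)) return(NA_real_)
      dice(m, n)
    }, numeric(1))
    names(perClass) <- paste0("class", classes)
    perClass <- c(perClass, macro = mean(perClass, na.rm = TRUE))
  }
  new("SegMetrics", dsc = dsc, hd = max(hf, hb), hdForward = hf,
      hdBackward = hb, perClass = perClass, units = units)
}
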