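# Readers and writers for the on-disk formats: 8-bit grayscale PNG and
# single-slice NIfTI images, paletted PNG / NIfTI label masks, and CSV
# case records. PNG round-trips preserve 8-bit values exactly; NIfTI
# round-trips preserve values and pixel spacing.

imageFormat <- function(path) {
  low <- tolower(path)
  if (grepl("\\.png$", low)) return("png")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  stop("unsupported image format: ", basename(path), call. = FALSE)
}

#' Read and write intensity images
#'
#' PNG images are stored as 8-bit grayscale (values 0-255, fractional
#' intensities rounded and clamped on write); NIfTI images preserve the
#' numeric values and carry the pixel spacing in their header.
#'
#' @param path file path ending in `.png`, `.nii` or `.nii.gz`.
#' @param image numeric intensity matrix.
#' @param pixelSpacing mm/pixel stored in the NIfTI header (ignored for
#'   PNG).
#' @return `loadImage` returns the intensity matrix (with the pixel
#'   spacing as attribute `pixelSpacing` for NIfTI); `saveImage` the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".png")
#' saveImage(matrix(seq(0, 255, length.out = 16), 4), f)
#' dim(loadImage(f))
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  switch(imageFormat(path),
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]  # grayscale channel
      round(a * 255)
    },
    nifti = {
      v <- RNifti::readNifti(path)
      spacing <- RNifti::pixdim(v)[1]
      m <- as.matrix(drop(as.array(v)))
      attr(m, "pixelSpacing") <- spacing
      m
    })
}

#' @rdname loadImage
#' @export
saveImage <- function(image, path, pixelSpacing = 1) {
  stopIfNot2D(image, "image")
  if (!dir.exists(dirname(path)))
    stop("no such directory: ", dirname(path), call. = FALSE)
  switch(imageFormat(path),
    png = {
      v <- round(pmin(pmax(image, 0), 255))
      png::writePNG(v / 255, path)
    },
    nifti = {
      v <- RNifti::asNifti(array(image, c(dim(image), 1L)),
                           reference = list(pixdim = c(-1, pixelSpacing,
                                                       pixelSpacing, 1,
                                                       0, 0, 0, 0)))
      RNifti::writeNifti(v, path)
    })
  invisible(path)
}

#' Read and write three-class label masks
#'
#' Masks hold the labels 0 (surrounding), 1 (central gland) and
#' 2 (marginal gland). PNG masks store the raw label values in an 8-bit
#' grayscale channel; any other value on load is rejected.
#'
#' @param mask integer matrix with values in \{0, 1, 2\}.
#' @param path file path ending in `.png`, `.nii` or `.nii.gz`.
#' @param pixelSpacing mm/pixel for NIfTI output.
#' @return `loadMask` returns an integer matrix; `saveMask` the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".png")
#' saveMask(matrix(c(0L, 1L, 2L, 0L), 2), f)
#' loadMask(f)
#' @export
saveMask <- function(mask, path, pixelSpacing = 1) {
  stopIfNot2D(mask, "mask")
  if (!all(mask %in% 0:2))
    stop("mask labels must be in {0, 1, 2}", call. = FALSE)
  switch(imageFormat(path),
    png = png::writePNG(matrix(as.integer(mask) / 255, nrow(mask)), path),
    nifti = {
      v <- RNifti::asNifti(array(as.integer(mask), c(dim(mask), 1L)),
                           reference = list(pixdim = c(-1, pixelSpacing,
                                                       pixelSpacing, 1,
                                                       0, 0, 0, 0)))
      RNifti::writeNifti(v, path)
    })
  invisible(path)
}

#' @rdname saveMask
#' @export
loadMask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- switch(imageFormat(path),
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]
      round(a * 255)
    },
    nifti = as.matrix(drop(as.array(RNifti::readNifti(path)))))
  if (!all(m %in% 0:2))
    stop("mask file contains labels outside {0, 1, 2}", call. = FALSE)
  matrix(as.integer(m), nrow(m))
}

#' Read and write cohort case records
#'
#' CSV with header `case_id,true_class,gleason_primary,gleason_secondary,
#' gleason_score,psa,clinical_stage` plus any additional columns (e.g.
#' `risk_group`, `has_lesion`).
#'
#' @param records data.frame of case records.
#' @param path CSV file path.
#' @return `readCaseRecords` returns the data.frame; `writeCaseRecords`
#'   the path, invisibly.
#' @export
writeCaseRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCaseRecords
#' @export
readCaseRecords <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "true_class", "gleason_primary", "gleason_secondary",
            "gleason_score", "psa", "clinical_stage")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("case record CSV is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- rec$gleason_score != rec$gleason_primary + rec$gleason_secondary
  if (any(bad))
    stop("gleason_score must equal gleason_primary + gleason_secondary",
         call. = FALSE)
  rec
}
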