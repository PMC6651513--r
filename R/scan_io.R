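#' Read a retinal scan from disk
#'
#' Reads a PNG, TIFF or JPEG image and returns a \linkS4class{RetinalScan}
#' with intensities rescaled to [0, 1]. Grayscale files stay 2-D; colour
#' files keep their three channels. The modality tag is \code{"unknown"}
#' until \code{\link{recognizeModality}} (or a manifest) sets it.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @param umPerPixel optional named micrometer-per-pixel calibration,
#'   e.g. \code{c(lateral = 11.6)}.
#' @return A \linkS4class{RetinalScan}.
#' @examples
#' p <- tempfile(fileext = ".png")
#' writeMask(p, matrix(rbinom(100, 1, 0.3), 10, 10))
#' readScan(p)
#' @export
readScan <- function(path, umPerPixel = numeric(0)) {
  if (!file.exists(path)) stop("cannot read scan: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff", "jpg", "jpeg"))
    stop("unsupported image format for ", path, " (PNG/TIFF/JPEG expected)")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("failed to read image ", path, ": ",
                         conditionMessage(e)))
  d <- dim(img)
  px <- if (length(d) == 2L) {
    t(EBImage::imageData(img))
  } else if (length(d) == 3L && d[3] >= 3L) {
    aperm(EBImage::imageData(img)[, , 1:3, drop = FALSE], c(2, 1, 3))
  } else if (length(d) == 3L && d[3] == 1L) {
    t(EBImage::imageData(img)[, , 1L])
  } else stop("unsupported image geometry in ", path)
  # readImage already maps 8/16-bit to [0, 1]; clamp residual excursions
  px <- clamp01(px)
  RetinalScan(px, modality = "unknown", umPerPixel = umPerPixel,
              sourceId = path)
}

#' Write a binary mask losslessly
#'
#' @param path output path ending in .png or .tif/.tiff.
#' @param mask binary (0/1) matrix in raster (rows x columns) convention.
#' @return Invisibly, the path.
#' @export
writeMask <- function(path, mask) {
  if (!isBinaryGrid(mask))
    stop("mask must be a binary (0/1) matrix")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff"))
    stop("masks must be written as PNG or TIFF, got .", ext)
  if (!dir.exists(dirname(path)))
    stop("cannot write mask: directory does not exist: ", dirname(path))
  EBImage::writeImage(EBImage::Image(t(mask)), path, bits = 8L)
  invisible(path)
}

#' Write a scan image to disk (8-bit)
#'
#' @param path output path ending in .png or .tif/.tiff.
#' @param scan a \linkS4class{RetinalScan}.
#' @return Invisibly, the path.
#' @export
writeScan <- function(path, scan) {
  stopifnot(is(scan, "RetinalScan"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff"))
    stop("scans are written as PNG or TIFF, got .", ext)
  p <- scan@pixels
  img <- if (length(dim(p)) == 3L)
    EBImage::Image(aperm(p, c(2, 1, 3)), colormode = "Color")
  else EBImage::Image(t(p))
  EBImage::writeImage(img, path, bits = 8L)
  invisible(path)
}

manifestModalities <- c("oct", "fundus")
manifestLabels <- c("healthy", "me")
manifestSplits <- c("train", "validation")

#' Load and validate a dataset manifest
#'
#' The manifest is a CSV with the exact header
#' \code{path,modality,label,split}. Only the two study classes are
#' admitted as labels: scans of other retinal pathologies are excluded
#' from the problem definition, so any other label token is a parse error.
#'
#' @param path CSV file path.
#' @param checkFiles if TRUE, also require every referenced image to exist.
#' @return A data.frame with columns path, modality, label, split.
#' @export
loadManifest <- function(path, checkFiles = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("path", "modality", "label", "split")
  if (!identical(names(df), need))
    stop("manifest header must be exactly 'path,modality,label,split'")
  checkEnum <- function(col, allowed, what) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad))
      stop("manifest line ", bad[1] + 1L, ": unknown ", what, " '",
           df[[col]][bad[1]], "' (allowed: ",
           paste(allowed, collapse = ", "), ")")
  }
  checkEnum("modality", manifestModalities, "modality")
  checkEnum("label", manifestLabels, "label")
  checkEnum("split", manifestSplits, "split")
  if (anyDuplicated(df$path))
    stop("manifest paths must be unique; duplicate: ",
         df$path[duplicated(df$path)][1])
  if (checkFiles) {
    missing <- df$path[!file.exists(df$path)]
    if (length(missing)) stop("manifest references missing file: ",
                              missing[1])
  }
  counts <- table(df$modality, df$label, df$split)
  message("manifest: ", nrow(df), " records; per (modality,label,split): ",
          paste(apply(expand.grid(dimnames(counts)), 1, paste,
                      collapse = "/"),
                as.vector(counts), sep = "=", collapse = ", "))
  df
}
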