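#' Blank acquisition annotation rows
#'
#' OCT acquisition devices burn annotations (scale bars, device text) into
#' the top and bottom rows of a B-scan. They are removed by setting the
#' first and last \code{nRows} rows to zero.
#'
#' @param scan a \linkS4class{RetinalScan}.
#' @param nRows number of rows to blank at each end (default 50).
#' @return The scan with annotation rows zeroed.
#' @export
stripAnnotationRows <- function(scan, nRows = 50L) {
  stopifnot(is(scan, "RetinalScan"))
  nRows <- as.integer(nRows)
  if (nRows < 0L) stop("nRows must be nonnegative")
  if (nRows == 0L) return(scan)
  p <- scan@pixels
  nr <- dim(p)[1]
  if (nr <= 2L * nRows)
    stop("scan has only ", nr, " rows; refusing to blank all of them")
  idx <- c(seq_len(nRows), (nr - nRows + 1L):nr)
  if (length(dim(p)) == 3L) p[idx, , ] <- 0 else p[idx, ] <- 0
  initialize(scan, pixels = p)
}

#' Repair degraded (saturated) scan regions
#'
#' Motion and acquisition failures leave near-saturated blocks at the scan
#' margins. For each column the first and last sharp vertical transitions
#' (absolute one-step intensity difference above \code{gradientThresh}) are
#' located; the segment above the first and below the last transition is
#' replaced by the mean of the background pixels when that segment is
#' itself near-saturated (mean above \code{satLevel}). Background pixels
#' are those below the Otsu threshold of the scan. Columns without a
#' qualifying transition pass through unchanged, as do clean scans whose
#' anatomical transitions are gentler than the threshold.
#'
#' @param scan a grayscale \linkS4class{RetinalScan}.
#' @param gradientThresh sharp-transition threshold in normalized intensity
#'   per pixel step (default 0.5).
#' @param satLevel minimum mean intensity for a flagged segment to count as
#'   degraded (default 0.8).
#' @return The repaired scan.
#' @export
repairDegradedRegions <- function(scan, gradientThresh = 0.5,
                                  satLevel = 0.8) {
  stopifnot(is(scan, "RetinalScan"))
  p <- scan@pixels
  if (length(dim(p)) == 3L)
    stop("repairDegradedRegions expects a grayscale scan")
  if (gradientThresh <= 0) stop("gradientThresh must be positive")
  nr <- nrow(p)
  if (nr < 3L) return(scan)
  th <- as.numeric(EBImage::otsu(EBImage::Image(t(p))))
  bg <- p < th
  bgMean <- if (any(bg)) mean(p[bg]) else 0
  out <- p
  for (j in seq_len(ncol(p))) {
    d <- abs(diff(p[, j]))
    hits <- which(d > gradientThresh)
    if (!length(hits)) next
    f <- hits[1]; l <- hits[length(hits)]
    top <- seq_len(f)
    if (mean(p[top, j]) > satLevel) out[top, j] <- bgMean
    bot <- (l + 1L):nr
    if (mean(p[bot, j]) > satLevel) out[bot, j] <- bgMean
  }
  initialize(scan, pixels = clamp01(out))
}

#' Parameters of the adaptive Wiener denoiser
#'
#' @param wh odd horizontal window width in pixels.
#' @param wv odd vertical window height in pixels.
#' @param noiseFloor the noise power a^2; \code{NULL} (default) estimates
#'   it as the mean of all local variances of the image.
#' @return A list of class \code{"DenoiseParams"}.
#' @export
denoiseParams <- function(wh = 5L, wv = 5L, noiseFloor = NULL) {
  wh <- as.integer(wh); wv <- as.integer(wv)
  if (wh < 1L || wv < 1L || wh %% 2L == 0L || wv %% 2L == 0L)
    stop("window sides must be odd positive integers")
  if (!is.null(noiseFloor) && noiseFloor < 0)
    stop("the noise floor a^2 must be nonnegative")
  structure(list(wh = wh, wv = wv, noiseFloor = noiseFloor),
            class = "DenoiseParams")
}

#' Adaptive local Wiener denoising
#'
#' Speckle in OCT (and sensor noise in fundus photography) is suppressed
#' with the pixel-wise adaptive Wiener filter. Over each \code{wv x wh}
#' window the local mean \eqn{m} and variance \eqn{s^2} are estimated
#' (symmetric boundary padding) and the output is
#' \deqn{D = m + \frac{\max(s^2 - a^2, 0)}{s^2} (O - m),}
#' with \eqn{D = m} where \eqn{s^2 = 0}. The noise power \eqn{a^2}
#' defaults to the mean of all local variances, so flat regions shrink
#' fully to their local mean while strong structure is preserved.
#'
#' @param scan a grayscale \linkS4class{RetinalScan} or a numeric matrix.
#' @param params a \code{\link{denoiseParams}} object.
#' @return Denoised scan of the same class as the input.
#' @export
wienerDenoise <- function(scan, params = denoiseParams()) {
  isScan <- is(scan, "RetinalScan")
  O <- if (isScan) scan@pixels else scan
  if (length(dim(O)) == 3L)
    stop("wienerDenoise expects a grayscale image")
  if (!inherits(params, "DenoiseParams")) stop("params must be DenoiseParams")
  n <- params$wh * params$wv
  m <- localBoxSum(O, params$wv, params$wh) / n
  s2 <- localBoxSum(O^2, params$wv, params$wh) / n - m^2
  s2 <- pmax(s2, 0)
  a2 <- if (is.null(params$noiseFloor)) mean(s2) else params$noiseFloor
  gain <- ifelse(s2 > 0, pmax(s2 - a2, 0) / pmax(s2, .Machine$double.xmin),
                 0)
  D <- m + gain * (O - m)
  if (isScan) initialize(scan, pixels = clamp01(D)) else D
}

#' Preprocess one scan for the extraction stage
#'
#' Applies the modality-appropriate cleanup chain: for OCT, annotation-row
#' stripping, degraded-region repair and Wiener denoising; for fundus, the
#' green working channel is denoised (annotations are a B-scan artifact and
#' are not stripped unless \code{stripFundus} is set).
#'
#' @param scan a \linkS4class{RetinalScan} with a known modality.
#' @param config a \code{\link{retfuseConfig}} list.
#' @param stripFundus also blank annotation rows on fundus scans.
#' @return A grayscale, denoised \linkS4class{RetinalScan}.
#' @export
preprocessScan <- function(scan, config = retfuseConfig(),
                           stripFundus = FALSE) {
  stopifnot(is(scan, "RetinalScan"))
  mod <- scan@modality
  if (mod == "unknown")
    stop("modality must be recognized before preprocessing")
  g <- RetinalScan(grayChannel(scan), modality = mod,
                   umPerPixel = scan@umPerPixel, sourceId = scan@sourceId)
  # repair first: degraded blocks are recognized by their contact with
  # the scan border, which annotation stripping would sever
  g <- repairDegradedRegions(g, config$preprocess$gradientThresh,
                             config$preprocess$satLevel)
  if (mod == "oct" || stripFundus)
    g <- stripAnnotationRows(g, config$preprocess$nRows)
  wienerDenoise(g, denoiseParams(config$preprocess$wh, config$preprocess$wv,
                                 config$preprocess$noiseFloor))
}
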