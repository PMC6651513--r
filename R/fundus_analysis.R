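# Estimate the circular field of view of a fundus image: pixels clearly
# above black, hull-filled. Phantoms and real fundus photographs both have
# a dark surround outside the camera aperture.
fieldOfViewMask <- function(gray, floor = 0.05) {
  m <- (gray > floor) * 1
  EBImage::imageData(EBImage::fillHull(EBImage::Image(m))) > 0
}

#' Segment retinal blood vessels from the fused tensor response
#'
#' Vessels are thin dark curvilinear structures; the TMAX response
#' (element-wise max of the two diagonal tensor channels) ridges along
#' them regardless of orientation. The response is hysteresis-thresholded
#' and components whose extent (bounding-box diagonal) is shorter than
#' \code{minLength} pixels are removed; the mask is restricted to the
#' circular field of view.
#'
#' @param response TMAX grid in [0, 1] from
#'   \code{\link{selectTensor}(mode = "fundus_vessels")}.
#' @param low,high hysteresis thresholds, \code{0 <= low < high <= 1}.
#' @param minLength minimum component extent in pixels.
#' @param fov optional logical field-of-view mask; estimated from
#'   \code{scan} when supplied, otherwise all-TRUE.
#' @param scan optional source \linkS4class{RetinalScan} used to estimate
#'   the field of view and to gate the mask to dark pixels.
#' @param gray optional grayscale working channel for the darkness gate:
#'   because the Gaussian window smears the tensor ridge well beyond the
#'   vessel walls, the hysteresis mask is intersected with pixels darker
#'   than \code{darkGate} times the field-of-view mean, which vessels
#'   (dark structures) satisfy and the surrounding halo does not.
#' @param darkGate relative darkness threshold (default 0.85); set to
#'   \code{Inf} to disable the gate.
#' @return Binary vessel mask.
#' @export
extractVessels <- function(response, low = 0.04, high = 0.2,
                           minLength = 12, fov = NULL, scan = NULL,
                           gray = NULL, darkGate = 0.85) {
  if (low < 0 || high > 1 || low >= high)
    stop("need 0 <= low < high <= 1")
  if (is.null(gray) && !is.null(scan)) gray <- grayChannel(scan)
  if (is.null(fov))
    fov <- if (is.null(gray)) matrix(TRUE, nrow(response), ncol(response))
           else fieldOfViewMask(gray)
  # shave the FOV rim: the aperture edge itself is a strong tensor ridge
  fovIn <- EBImage::imageData(EBImage::erode(
    EBImage::Image(fov * 1), EBImage::makeBrush(9L, "disc"))) > 0
  mask <- hysteresisThreshold(response * fovIn, low, high)
  if (!is.null(gray) && is.finite(darkGate))
    mask <- mask * (gray < darkGate * mean(gray[fov]))
  la <- labelComponents(mask)
  n <- max(la)
  if (n > 0L) {
    pix <- which(la > 0, arr.ind = TRUE)
    labv <- la[la > 0]
    r1 <- tapply(pix[, 1], labv, min); r2 <- tapply(pix[, 1], labv, max)
    c1 <- tapply(pix[, 2], labv, min); c2 <- tapply(pix[, 2], labv, max)
    ext <- sqrt((r2 - r1)^2 + (c2 - c1)^2)
    mask <- filterComponents(la, function(i) ext[[as.character(i)]] >=
                               minLength)
  }
  mask
}

#' Localize the optic disc
#'
#' The optic disc is the brightest extended region of a fundus image. The
#' mean intensity under a sliding disc of the given radius is computed by
#' disc filtering and its argmax taken as the centre; when the best
#' regional mean is below \code{floor} no disc is reported (absence is a
#' value, not an error).
#'
#' @param scan a \linkS4class{RetinalScan} (colour or grayscale).
#' @param radius disc radius in pixels (default 40).
#' @param floor minimum regional mean intensity to accept (default 0.6).
#' @return Named numeric \code{c(cx, cy, r)} (cx = column, cy = row), or
#'   \code{NULL} when absent.
#' @export
localizeOpticDisc <- function(scan, radius = 40, floor = 0.6) {
  g <- if (is(scan, "RetinalScan")) grayChannel(scan) else scan
  brush <- EBImage::makeBrush(2L * ceiling(radius) + 1L, shape = "disc")
  brush <- brush / sum(brush)
  sm <- correlate2(g, brush)
  fov <- fieldOfViewMask(g)
  sm[!fov] <- -Inf
  best <- which.max(sm)
  if (!is.finite(sm[best]) || sm[best] < floor) return(NULL)
  ij <- arrayInd(best, dim(sm))
  c(cx = ij[1, 2], cy = ij[1, 1], r = radius)
}

#' Extract hard exudates from a fundus scan
#'
#' Hard exudates are small bright lipid deposits. Uneven illumination is
#' removed with a white top-hat transform (disc structuring element of
#' radius \code{topHatRadius}); pixels whose enhanced response exceeds
#' \code{tBright} times the field-of-view mean of the enhanced image are
#' candidates. Candidates intersecting the blood-vessel mask or the
#' dilated optic-disc region (radius scaled by \code{discDilate}) are
#' removed — both are bright-rimmed confounds — and surviving components
#' are filtered to the [\code{minArea}, \code{maxArea}] pixel range.
#'
#' @param scan the fundus \linkS4class{RetinalScan}.
#' @param vessels binary vessel mask from \code{\link{extractVessels}}.
#' @param disc optic-disc descriptor from \code{\link{localizeOpticDisc}},
#'   or NULL.
#' @param tBright relative brightness threshold (default 1.3).
#' @param topHatRadius structuring-element radius in pixels (default 8).
#' @param minArea,maxArea component area band in pixels.
#' @param discDilate dilation factor applied to the disc radius.
#' @return Binary exudate mask, disjoint from vessels and disc.
#' @export
extractExudates <- function(scan, vessels, disc = NULL, tBright = 1.3,
                            topHatRadius = 8, minArea = 5L, maxArea = 2000L,
                            discDilate = 1.5) {
  g <- if (is(scan, "RetinalScan")) grayChannel(scan) else scan
  if (!identical(dim(g), dim(vessels)))
    stop("scan and vessel mask shapes differ")
  fov <- fieldOfViewMask(g)
  # the aperture rim itself rings under the top-hat; shave it off
  fov <- EBImage::imageData(EBImage::erode(EBImage::Image(fov * 1),
           EBImage::makeBrush(2L * ceiling(topHatRadius) + 3L, "disc"))) > 0
  brush <- EBImage::makeBrush(2L * ceiling(topHatRadius) + 1L, "disc")
  enh <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(t(g)),
                                                 brush))
  enh <- t(enh)
  # candidates must be bright relative to the field of view AND pop out
  # of the top-hat (i.e. be small-scale); the top-hat alone also fires on
  # bright slivers pinched between neighbouring dark vessels
  cand <- (g > tBright * mean(g[fov])) & (enh > 0.05) & fov
  vDil <- EBImage::imageData(EBImage::dilate(EBImage::Image(vessels),
            EBImage::makeBrush(5L, "disc")))
  cand[vDil > 0] <- FALSE
  if (!is.null(disc)) {
    ex <- matrix(0, nrow(g), ncol(g))
    ex <- stampDisc(ex, disc["cy"], disc["cx"], disc["r"] * discDilate)
    cand[ex > 0] <- FALSE
  }
  la <- labelComponents(cand * 1)
  areas <- componentAreas(la)
  filterComponents(la, function(i) areas[i] >= minArea && areas[i] <= maxArea)
}
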