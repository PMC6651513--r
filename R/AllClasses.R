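#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' RetinalScan: a retinal image with modality and calibration metadata
#'
#' The container every pipeline stage transforms. Pixels are stored as a
#' rows-by-columns matrix (grayscale) or a rows-by-columns-by-3 array
#' (colour fundus), with intensities in [0, 1]. Row 1 is the top of the
#' image and, for OCT B-scans, depth increases with the row index.
#'
#' @slot pixels numeric matrix or 3-channel array with values in [0, 1].
#' @slot modality one of \code{"unknown"}, \code{"oct"}, \code{"fundus"}.
#' @slot umPerPixel optional named numeric of physical pixel pitch in
#'   micrometers; names among \code{"axial"} and \code{"lateral"}. Length 0
#'   means uncalibrated.
#' @slot sourceId free-text identifier (usually the file path).
#'
#' @examples
#' s <- RetinalScan(matrix(runif(20), 4, 5), modality = "oct")
#' dim(s)
#' @export
setClass("RetinalScan",
  representation(pixels = "array", modality = "character",
                 umPerPixel = "numeric", sourceId = "character"))

setValidity("RetinalScan", function(object) {
  p <- object@pixels
  d <- dim(p)
  if (!(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    return("pixels must be a 2-D matrix or a rows x cols x 3 array")
  if (d[1] < 1L || d[2] < 1L) return("image must have at least one pixel")
  if (!all(is.finite(p))) return("intensities must be finite")
  if (min(p) < 0 || max(p) > 1) return("intensities must lie in [0, 1]")
  if (length(object@modality) != 1L ||
      !object@modality %in% c("unknown", "oct", "fundus"))
    return("modality must be one of 'unknown', 'oct', 'fundus'")
  u <- object@umPerPixel
  if (length(u)) {
    if (any(!is.finite(u)) || any(u <= 0))
      return("umPerPixel values must be positive and finite")
    if (is.null(names(u)) || !all(names(u) %in% c("axial", "lateral")))
      return("umPerPixel must be named with 'axial' and/or 'lateral'")
  }
  TRUE
})

#' Construct a RetinalScan
#'
#' @param pixels matrix or rows x cols x 3 array with values in [0, 1].
#' @param modality modality tag; defaults to \code{"unknown"}.
#' @param umPerPixel optional named micrometer-per-pixel calibration.
#' @param sourceId free-text identifier.
#' @return A \linkS4class{RetinalScan}.
#' @export
RetinalScan <- function(pixels, modality = "unknown",
                        umPerPixel = numeric(0), sourceId = "") {
  storage.mode(pixels) <- "double"
  u <- umPerPixel
  if (length(u)) storage.mode(u) <- "double"
  new("RetinalScan", pixels = pixels, modality = modality,
      umPerPixel = u, sourceId = sourceId)
}

#' StructureTensorField: per-pixel second-moment tensor components
#'
#' Holds the Gaussian-windowed products of Gaussian-derivative responses:
#' \code{txx} (horizontal energy), \code{tyy} (vertical energy) and the
#' off-diagonal \code{txy}. The per-pixel 2x2 matrix
#' \code{[[txx, txy], [txy, tyy]]} is positive semidefinite by construction.
#'
#' @slot txx,tyy,txy numeric matrices sharing the source image shape.
#' @slot sigmaD derivative Gaussian scale (pixels).
#' @slot sigmaW window Gaussian scale (pixels).
#' @export
setClass("StructureTensorField",
  representation(txx = "matrix", tyy = "matrix", txy = "matrix",
                 sigmaD = "numeric", sigmaW = "numeric"))

setValidity("StructureTensorField", function(object) {
  d <- dim(object@txx)
  if (!identical(d, dim(object@tyy)) || !identical(d, dim(object@txy)))
    return("txx, tyy, txy must share one shape")
  tol <- 1e-9 * max(1, max(abs(object@txx)), max(abs(object@tyy)))
  if (min(object@txx) < -tol || min(object@tyy) < -tol)
    return("diagonal tensor components must be nonnegative")
  detv <- object@txx * object@tyy - object@txy^2
  if (min(detv) < -1e-9 * max(1, max(abs(detv))))
    return("per-pixel tensor must be positive semidefinite")
  if (object@sigmaD <= 0 || object@sigmaW <= 0)
    return("Gaussian scales must be positive")
  TRUE
})

#' CoherenceSummary: eigenvalue anisotropy of a tensor field
#'
#' @slot coherence matrix of per-pixel coherence
#'   \eqn{((\lambda_1-\lambda_2)/(\lambda_1+\lambda_2))^2} in [0, 1].
#' @slot channelScores named numeric: mean coherence-weighted energy of the
#'   \code{txx}, \code{tyy} and \code{txy} channels.
#' @export
setClass("CoherenceSummary",
  representation(coherence = "matrix", channelScores = "numeric"))

setValidity("CoherenceSummary", function(object) {
  cc <- object@coherence
  if (min(cc) < -1e-12 || max(cc) > 1 + 1e-12)
    return("coherence must lie in [0, 1]")
  if (!all(c("txx", "tyy", "txy") %in% names(object@channelScores)))
    return("channelScores must be named txx, tyy, txy")
  TRUE
})

#' LayerBoundarySet: per-column depth curves of OCT retinal boundaries
#'
#' Up to nine boundary curves, stored as a curves-by-columns matrix of row
#' indices (NA where a curve is undefined). Curves are ordered
#' top-to-bottom; the inner limiting membrane (ILM) and retinal pigment
#' epithelium (RPE) curves are designated by index.
#'
#' @slot boundaries numeric matrix (k x columns) of row indices, NA allowed.
#' @slot ilmIndex,rpeIndex integer row of \code{boundaries} holding the ILM
#'   and RPE curve.
#' @slot jumpLimit maximum permitted inter-column jump (pixels).
#' @export
setClass("LayerBoundarySet",
  representation(boundaries = "matrix", ilmIndex = "integer",
                 rpeIndex = "integer", jumpLimit = "numeric"))

setValidity("LayerBoundarySet", function(object) {
  b <- object@boundaries
  k <- nrow(b)
  if (k < 1L || k > 9L) return("between 1 and 9 boundary curves expected")
  ii <- object@ilmIndex; ri <- object@rpeIndex
  if (ii < 1L || ii > k || ri < 1L || ri > k)
    return("ilmIndex/rpeIndex out of range")
  ilm <- b[ii, ]; rpe <- b[ri, ]
  for (q in seq_len(k)) {
    both <- !is.na(b[q, ]) & !is.na(ilm)
    if (any(b[q, both] < ilm[both] - 1e-9))
      return("a boundary lies above the ILM")
    both <- !is.na(b[q, ]) & !is.na(rpe)
    if (any(b[q, both] > rpe[both] + 1e-9))
      return("a boundary lies below the RPE")
  }
  J <- object@jumpLimit
  for (q in seq_len(k)) {
    v <- b[q, ]
    dv <- abs(diff(v))
    if (any(dv[!is.na(dv)] > J + 1e-9))
      return("inter-column jump exceeds the continuity limit")
  }
  TRUE
})

#' FindingMasks: binary masks of clinically significant ME findings
#'
#' @slot fluid,vessels,exudates binary matrices matching the source scan
#'   shape (all-zero when the finding does not apply to the modality).
#' @slot opticDisc numeric of length 0 (absent) or named c(cx, cy, r) in
#'   pixel coordinates (cx = column, cy = row).
#' @slot foveaCol column index of the fovea centre, or NA when unknown.
#' @export
setClass("FindingMasks",
  representation(fluid = "matrix", vessels = "matrix", exudates = "matrix",
                 opticDisc = "numeric", foveaCol = "numeric"))

setValidity("FindingMasks", function(object) {
  d <- dim(object@fluid)
  if (!identical(d, dim(object@vessels)) ||
      !identical(d, dim(object@exudates)))
    return("masks must share one shape")
  for (nm in c("fluid", "vessels", "exudates"))
    if (!all(slot(object, nm) %in% c(0, 1)))
      return(paste(nm, "mask must be binary"))
  od <- object@opticDisc
  if (length(od) && (length(od) != 3L ||
      !all(c("cx", "cy", "r") %in% names(od))))
    return("opticDisc must be absent or named c(cx, cy, r)")
  TRUE
})

#' Construct an empty FindingMasks object for a scan shape
#' @param nrow,ncol mask shape.
#' @return A \linkS4class{FindingMasks} with all-zero masks.
#' @export
emptyFindingMasks <- function(nrow, ncol) {
  z <- matrix(0, nrow, ncol)
  new("FindingMasks", fluid = z, vessels = z, exudates = z,
      opticDisc = numeric(0), foveaCol = NA_real_)
}

#' FeatureVector: the fused 16-D descriptor
#'
#' Eight OCT features (f1..f8) followed by eight fundus features (f9..f16),
#' as produced by the per-modality feature CNNs.
#'
#' @slot oct,fundus numeric vectors of length 8.
#' @slot label optional class label (\code{"healthy"} or \code{"me"}).
#' @export
setClass("FeatureVector",
  representation(oct = "numeric", fundus = "numeric", label = "character"))

setValidity("FeatureVector", function(object) {
  if (length(object@oct) != 8L || length(object@fundus) != 8L)
    return("both modality blocks must have length 8")
  if (!all(is.finite(c(object@oct, object@fundus))))
    return("features must be finite")
  if (length(object@label) > 1L ||
      (length(object@label) == 1L &&
       !object@label %in% c("healthy", "me")))
    return("label must be absent, 'healthy' or 'me'")
  TRUE
})

#' RetinalDiagnosis: per-classifier votes and the majority decision
#'
#' @slot votes named character vector of the ANN, SVM and NB votes.
#' @slot final the majority label.
#' @slot posterior optional named per-classifier score for the voted class.
#' @export
setClass("RetinalDiagnosis",
  representation(votes = "character", final = "character",
                 posterior = "numeric"))

setValidity("RetinalDiagnosis", function(object) {
  v <- object@votes
  if (length(v) != 3L || !all(c("ann", "svm", "nb") %in% names(v)))
    return("votes must be named 'ann', 'svm', 'nb'")
  if (!all(v %in% c("healthy", "me")))
    return("votes must be 'healthy' or 'me'")
  tab <- table(v)
  if (object@final != names(tab)[which.max(tab)])
    return("final label must equal the majority of the votes")
  TRUE
})
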