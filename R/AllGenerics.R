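#' @include AllClasses.R
NULL

#' Accessors for retfuse classes
#'
#' \code{pixels} returns the intensity grid of a scan; \code{modality} and
#' \code{modality<-} read and set its modality tag; \code{umPerPixel}
#' returns the calibration; \code{grayChannel} returns the grayscale
#' working channel (the green channel of a colour fundus image);
#' \code{features} returns the 16 fused values of a
#' \linkS4class{FeatureVector}.
#'
#' @param object a retfuse object.
#' @param value replacement value.
#' @return The accessed component.
#' @name accessors
#' @aliases pixels modality modality<- umPerPixel grayChannel features
#' @examples
#' s <- RetinalScan(matrix(0.5, 4, 5))
#' pixels(s)[1, 1]
#' modality(s) <- "oct"
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("modality<-", function(object, value) standardGeneric("modality<-"))
#' @rdname accessors
#' @export
setGeneric("umPerPixel", function(object) standardGeneric("umPerPixel"))
#' @rdname accessors
#' @export
setGeneric("grayChannel", function(object) standardGeneric("grayChannel"))
#' @rdname accessors
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' @rdname accessors
#' @export
setMethod("pixels", "RetinalScan", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("modality", "RetinalScan", function(object) object@modality)

#' @rdname accessors
#' @export
setReplaceMethod("modality", "RetinalScan", function(object, value) {
  if (object@modality != "unknown" && object@modality != value)
    stop("modality tag is already '", object@modality,
         "' and must not silently change")
  object@modality <- value
  validObject(object)
  object
})

#' @rdname accessors
#' @export
setMethod("umPerPixel", "RetinalScan", function(object) object@umPerPixel)

#' @rdname accessors
#' @export
setMethod("grayChannel", "RetinalScan", function(object) {
  p <- object@pixels
  if (length(dim(p)) == 3L) p[, , 2L] else p
})

#' @rdname accessors
#' @export
setMethod("features", "FeatureVector", function(object) {
  stats::setNames(c(object@oct, object@fundus), paste0("f", 1:16))
})

setMethod("dim", "RetinalScan", function(x) dim(x@pixels)[1:2])

setMethod("show", "RetinalScan", function(object) {
  d <- dim(object@pixels)
  cat("RetinalScan:", d[1], "x", d[2],
      if (length(d) == 3L) "x 3 (colour)" else "(grayscale)", "\n")
  cat("  modality:", object@modality, "\n")
  if (length(object@umPerPixel))
    cat("  calibration (um/px):",
        paste(names(object@umPerPixel), round(object@umPerPixel, 3),
              sep = "=", collapse = ", "), "\n")
  if (nzchar(object@sourceId)) cat("  source:", object@sourceId, "\n")
  cat("  intensity range: [", round(min(object@pixels), 4), ",",
      round(max(object@pixels), 4), "]\n")
})

setMethod("show", "StructureTensorField", function(object) {
  d <- dim(object@txx)
  cat("StructureTensorField:", d[1], "x", d[2], "\n")
  cat("  sigmaD =", object@sigmaD, ", sigmaW =", object@sigmaW, "\n")
  cat("  mean energies: txx =", signif(mean(object@txx), 4),
      ", tyy =", signif(mean(object@tyy), 4), "\n")
})

setMethod("show", "LayerBoundarySet", function(object) {
  cat("LayerBoundarySet:", nrow(object@boundaries), "curves over",
      ncol(object@boundaries), "columns\n")
  cat("  ILM = curve", object@ilmIndex, ", RPE = curve",
      object@rpeIndex, ", jump limit", object@jumpLimit, "px\n")
})

setMethod("show", "FindingMasks", function(object) {
  cat("FindingMasks:", nrow(object@fluid), "x", ncol(object@fluid), "\n")
  cat("  fluid:", sum(object@fluid), "px; vessels:", sum(object@vessels),
      "px; exudates:", sum(object@exudates), "px\n")
  if (length(object@opticDisc))
    cat("  optic disc at (", object@opticDisc["cx"], ",",
        object@opticDisc["cy"], "), r =", object@opticDisc["r"], "\n")
  if (!is.na(object@foveaCol))
    cat("  fovea column:", object@foveaCol, "\n")
})

setMethod("show", "FeatureVector", function(object) {
  cat("FeatureVector (16-D):\n")
  cat("  OCT f1..f8:   ", paste(signif(object@oct, 3), collapse = " "), "\n")
  cat("  fundus f9..f16:", paste(signif(object@fundus, 3), collapse = " "),
      "\n")
  if (length(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "RetinalDiagnosis", function(object) {
  cat("RetinalDiagnosis:", object@final, "\n")
  cat("  votes:", paste(names(object@votes), object@votes, sep = "=",
                        collapse = ", "), "\n")
})
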