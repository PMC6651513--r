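#' Overlay extracted findings onto a scan
#'
#' Burns the extracted retinal information into a 3-channel copy of the
#' scan with a fixed colour coding: fluid red, vessels green, exudates
#' yellow, layer boundaries blue. The annotated scan is what the feature
#' CNN consumes, so the coding is deterministic; the original scan is
#' untouched.
#'
#' @param scan a \linkS4class{RetinalScan}.
#' @param masks a \linkS4class{FindingMasks} matching the scan shape.
#' @param layers optional \linkS4class{LayerBoundarySet} to draw.
#' @return A 3-channel \linkS4class{RetinalScan}.
#' @export
overlayFindings <- function(scan, masks, layers = NULL) {
  stopifnot(is(scan, "RetinalScan"), is(masks, "FindingMasks"))
  p <- scan@pixels
  d <- dim(p)[1:2]
  if (!identical(d, dim(masks@fluid)))
    stop("scan and mask shapes differ")
  px <- if (length(dim(p)) == 3L) p else array(rep(p, 3L), c(d, 3L))
  paint <- function(px, mask, rgb) {
    sel <- mask > 0
    for (ch in 1:3) {
      pl <- px[, , ch]
      pl[sel] <- rgb[ch]
      px[, , ch] <- pl
    }
    px
  }
  px <- paint(px, masks@vessels, c(0, 1, 0))
  px <- paint(px, masks@exudates, c(1, 1, 0))
  px <- paint(px, masks@fluid, c(1, 0, 0))
  if (!is.null(layers)) {
    bm <- matrix(0, d[1], d[2])
    for (q in seq_len(nrow(layers@boundaries))) {
      v <- layers@boundaries[q, ]
      ok <- which(!is.na(v))
      bm[cbind(pmin(pmax(round(v[ok]), 1L), d[1]), ok)] <- 1
    }
    px <- paint(px, bm, c(0, 0.4, 1))
  }
  RetinalScan(clamp01(px), modality = scan@modality,
              umPerPixel = scan@umPerPixel,
              sourceId = paste0(scan@sourceId, "+overlay"))
}

#' Fuse per-modality CNN features into the 16-D descriptor
#'
#' OCT features come first (f1..f8), fundus features second (f9..f16);
#' the order is part of the descriptor contract.
#'
#' @param octFeatures,fundusFeatures numeric vectors of length 8.
#' @param label optional class label to attach.
#' @return A \linkS4class{FeatureVector}.
#' @examples
#' features(fuseFeatures(1:8, 9:16))
#' @export
fuseFeatures <- function(octFeatures, fundusFeatures,
                         label = character(0)) {
  if (length(octFeatures) != 8L || length(fundusFeatures) != 8L)
    stop("both modality feature blocks must have length 8")
  new("FeatureVector", oct = as.numeric(octFeatures),
      fundus = as.numeric(fundusFeatures), label = label)
}
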