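#' Extract retinal layer boundaries from an OCT tensor response
#'
#' Boundary candidates are the Canny edge pixels of the layer response
#' (mode \code{"oct_layers"}), ranked by response strength. Curves are
#' assembled greedily from the top of the scan downwards: the topmost
#' unused candidate seeds a curve, which is traced left and right column
#' by column, at each step taking the nearest unused candidate within the
#' jump limit \code{J} (ties broken by stronger response; gaps of up to
#' \code{maxGap} columns are bridged). Each curve is median-smoothed over
#' \code{smoothWindow} columns and its steps clamped to \code{J}. Curves
#' covering less than half the columns are discarded. The topmost curve is
#' designated ILM; among the bottom two curves the one overlying the
#' brighter band is designated RPE.
#'
#' @param response layer response grid from \code{\link{selectTensor}}.
#' @param edges binary edge grid from \code{\link{cannyEdges}}.
#' @param k maximum number of curves to return (<= 9).
#' @param J maximum inter-column jump in pixels.
#' @param smoothWindow odd median-smoothing window (columns).
#' @param maxGap columns a trace may bridge without a candidate.
#' @param intensity optional denoised intensity grid used to pick the RPE
#'   by band brightness; when absent the bottommost curve is the RPE.
#' @return A \linkS4class{LayerBoundarySet}.
#' @export
extractLayers <- function(response, edges, k = 9L, J = 3L,
                          smoothWindow = 15L, maxGap = 8L,
                          intensity = NULL) {
  if (!identical(dim(response), dim(edges)))
    stop("response and edge grids must share one shape")
  k <- as.integer(k)
  if (k < 2L || k > 9L) stop("k must be between 2 and 9")
  nr <- nrow(response); nc <- ncol(response)
  cand <- which(edges != 0, arr.ind = TRUE)
  if (nrow(cand) == 0L) stop("no boundary candidates: scan unusable")
  # layered anatomy yields sparse horizontal chains; pervasive edges mean
  # the scan has no layered structure to trace
  if (nrow(cand) / (nr * nc) > 0.08)
    stop("edge density too high for layered anatomy: scan unusable")
  used <- matrix(FALSE, nr, nc)
  # per-column candidate rows, sorted
  byCol <- split(cand[, 1L], cand[, 2L])
  colKeys <- as.integer(names(byCol))
  candRows <- vector("list", nc)
  candRows[colKeys] <- byCol

  nextInCol <- function(j, row) {
    rs <- candRows[[j]]
    if (is.null(rs)) return(NA_integer_)
    rs <- rs[!used[cbind(rs, j)] & abs(rs - row) <= J]
    if (!length(rs)) return(NA_integer_)
    d <- abs(rs - row)
    rs <- rs[d == min(d)]
    if (length(rs) > 1L) rs <- rs[which.max(response[cbind(rs, j)])]
    rs[1L]
  }

  traceFrom <- function(seedRow, seedCol) {
    curve <- rep(NA_real_, nc)
    curve[seedCol] <- seedRow
    used[seedRow, seedCol] <<- TRUE
    for (dir in c(1L, -1L)) {
      row <- seedRow; gap <- 0L; j <- seedCol + dir
      while (j >= 1L && j <= nc && gap <= maxGap) {
        r <- nextInCol(j, row)
        if (is.na(r)) {
          gap <- gap + 1L
        } else {
          curve[j] <- r
          used[r, j] <<- TRUE
          row <- r
          gap <- 0L
        }
        j <- j + dir
      }
    }
    curve
  }

  curves <- list()
  repeat {
    if (length(curves) >= k) break
    free <- which(edges != 0 & !used, arr.ind = TRUE)
    if (nrow(free) == 0L) break
    top <- min(free[, 1L])
    sel <- free[free[, 1L] == top, , drop = FALSE]
    if (nrow(sel) > 1L)
      sel <- sel[which.max(response[sel]), , drop = FALSE]
    cv <- traceFrom(sel[1L, 1L], sel[1L, 2L])
    if (sum(!is.na(cv)) >= nc / 2) {
      # interpolate bridged gaps, then median-smooth and clamp jumps
      def <- which(!is.na(cv))
      cv[def[1]:def[length(def)]] <-
        stats::approx(def, cv[def], xout = def[1]:def[length(def)])$y
      inner <- def[1]:def[length(def)]
      cv[inner] <- stats::runmed(cv[inner], k = min(smoothWindow,
        2L * (length(inner) %/% 2L) - 1L), endrule = "median")
      for (j in inner[-1L]) {
        step <- cv[j] - cv[j - 1L]
        if (!is.na(step) && abs(step) > J)
          cv[j] <- cv[j - 1L] + sign(step) * J
      }
      curves[[length(curves) + 1L]] <- cv
    }
  }
  if (length(curves) < 2L)
    stop("fewer than 2 layer boundaries found: scan unusable")
  B <- do.call(rbind, curves)
  B <- B[order(rowMeans(B, na.rm = TRUE)), , drop = FALSE]
  # enforce top-to-bottom ordering: where a curve rises above the running
  # maximum of the curves above it, it is undefined (crossings indicate
  # unreliable evidence, and blanking preserves the jump limit within the
  # remaining defined stretches)
  env <- B[1L, ]
  for (q in seq_len(nrow(B))[-1L]) {
    viol <- !is.na(B[q, ]) & !is.na(env) & B[q, ] < env
    B[q, viol] <- NA_real_
    env <- pmax(env, B[q, ], na.rm = TRUE)
  }
  keep <- rowMeans(!is.na(B)) >= 0.4
  B <- B[keep, , drop = FALSE]
  if (nrow(B) < 2L)
    stop("fewer than 2 layer boundaries found: scan unusable")
  nrB <- nrow(B)
  # RPE: of the bottom two curves, the one overlying the brighter band
  bandBrightness <- function(q) {
    v <- B[q, ]
    ok <- which(!is.na(v))
    rows <- pmax(1, round(v[ok]) - 4)
    grid <- if (is.null(intensity)) response else intensity
    mean(grid[cbind(rows, ok)])
  }
  cand2 <- if (nrB >= 2L) c(nrB - 1L, nrB) else nrB
  rpe <- cand2[which.max(vapply(cand2, bandBrightness, numeric(1)))]
  # curves below the RPE are sub-retinal artifacts; drop them
  if (rpe < nrB) B <- B[seq_len(rpe), , drop = FALSE]
  new("LayerBoundarySet", boundaries = B, ilmIndex = 1L,
      rpeIndex = as.integer(rpe), jumpLimit = as.numeric(J))
}

#' Localize the fovea on an ILM depth curve
#'
#' The fovea is the deepest point of the inner limiting membrane: the ILM
#' curve is mean-smoothed and the column of maximal depth (largest row
#' index) returned, ties broken toward the image-centre column.
#'
#' @param ilm numeric vector of ILM row indices per column (NA allowed),
#'   or a \linkS4class{LayerBoundarySet} whose ILM curve is used.
#' @param smoothWindow odd smoothing window in columns (default 15).
#' @return The fovea column index (1-based).
#' @export
localizeFovea <- function(ilm, smoothWindow = 15L) {
  if (is(ilm, "LayerBoundarySet")) ilm <- ilm@boundaries[ilm@ilmIndex, ]
  n <- length(ilm)
  if (sum(!is.na(ilm)) < n / 2)
    stop("ILM must be defined on at least half the columns")
  sm <- movingAverageNA(ilm, smoothWindow)
  mx <- max(sm, na.rm = TRUE)
  hits <- which(sm >= mx - 1e-12)
  centre <- (n + 1) / 2
  hits[order(abs(hits - centre), hits)][1L]
}

#' Build the ILM-RPE retinal mask
#'
#' @param layers a \linkS4class{LayerBoundarySet}.
#' @return Binary matrix, 1 strictly between the ILM and RPE per column.
#' @param nrow number of rows of the source scan.
#' @export
buildRetinalMask <- function(layers, nrow) {
  stopifnot(is(layers, "LayerBoundarySet"))
  ilm <- layers@boundaries[layers@ilmIndex, ]
  rpe <- layers@boundaries[layers@rpeIndex, ]
  nc <- length(ilm)
  mask <- matrix(0, nrow, nc)
  for (j in seq_len(nc)) {
    if (is.na(ilm[j]) || is.na(rpe[j])) next
    a <- floor(ilm[j]) + 1L
    b <- ceiling(rpe[j]) - 1L
    if (a <= b) mask[max(1L, a):min(nrow, b), j] <- 1
  }
  mask
}

#' Extract intraretinal fluid from a denoised B-scan
#'
#' The retinal mask is multiplied onto the denoised scan and
#' hypo-reflective pixels below \code{t} times the mean in-band intensity
#' are taken as fluid candidates; a 3x3 morphological opening removes
#' speckle residue and components smaller than \code{minArea} pixels are
#' dropped. The result is a subset of the retinal band by construction.
#'
#' @param denoised a grayscale \linkS4class{RetinalScan} or matrix.
#' @param mask binary ILM-RPE band mask from \code{\link{buildRetinalMask}}.
#' @param t relative darkness threshold (default 0.5).
#' @param minArea minimum component area in pixels (default 30).
#' @return Binary fluid mask.
#' @export
extractFluid <- function(denoised, mask, t = 0.5, minArea = 30L) {
  D <- if (is(denoised, "RetinalScan")) grayChannel(denoised) else denoised
  if (!identical(dim(D), dim(mask))) stop("scan and mask shapes differ")
  if (!any(mask > 0)) stop("empty retinal mask")
  inBand <- D[mask > 0]
  thr <- t * mean(inBand)
  candidates <- (D < thr) * (mask > 0)
  kern <- EBImage::makeBrush(3L, shape = "box")
  opened <- EBImage::imageData(EBImage::opening(EBImage::Image(candidates),
                                                kern))
  la <- labelComponents(opened)
  areas <- componentAreas(la)
  fluid <- filterComponents(la, function(i) areas[i] >= minArea)
  fluid * (mask > 0)
}

#' Grade the clinical significance of macular edema findings
#'
#' The EDTRS criterion: edema is clinically significant when lesions
#' (fluid or hard exudates) lie within \code{radiusUm} micrometers of the
#' fovea centre; 500 um by default. Only lateral (column) distance is
#' used, matching the clinical definition on B-scans.
#'
#' @param masks a \linkS4class{FindingMasks}.
#' @param foveaCol fovea column; defaults to the one stored in
#'   \code{masks}.
#' @param umPerPixel lateral micrometers per pixel.
#' @param radiusUm distance defining significance (default 500).
#' @return \code{"clinically_significant"}, \code{"non_significant"} or
#'   \code{"none"} when no lesion is present.
#' @export
gradeClinicalSignificance <- function(masks, foveaCol = masks@foveaCol,
                                      umPerPixel, radiusUm = 500) {
  stopifnot(is(masks, "FindingMasks"))
  lesions <- masks@fluid + masks@exudates
  if (!any(lesions > 0)) return("none")
  if (missing(umPerPixel) || is.null(umPerPixel) || !length(umPerPixel) ||
      !is.finite(umPerPixel[1]))
    stop("lateral calibration (umPerPixel) is required to grade lesions")
  if (is.na(foveaCol)) stop("fovea column is required to grade lesions")
  cols <- which(colSums(lesions) > 0)
  distUm <- abs(cols - foveaCol) * umPerPixel[1]
  if (any(distUm <= radiusUm)) "clinically_significant" else "non_significant"
}
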