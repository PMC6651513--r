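#' Compute the second-moment structure tensor of a scan
#'
#' The structure tensor (second-moment / structure coherence matrix)
#' encodes local orientation: image gradients are estimated with Gaussian
#' derivative filters at scale \code{sigmaD} and their squares and product
#' are averaged under a Gaussian window at scale \code{sigmaW},
#' \deqn{T_{xx} = g_w * \varphi_x^2,\quad T_{yy} = g_w * \varphi_y^2,\quad
#'       T_{xy} = g_w * (\varphi_x \varphi_y),}
#' where x is the horizontal (column) and y the vertical (row) direction.
#' The outer-product off-diagonal keeps the per-pixel 2x2 matrix positive
#' semidefinite, which the eigenvalue-based coherence analysis relies on.
#'
#' @param denoised a grayscale \linkS4class{RetinalScan} or numeric matrix
#'   (typically the output of \code{\link{wienerDenoise}}).
#' @param sigmaD derivative Gaussian scale in pixels (default 1).
#' @param sigmaW window Gaussian scale in pixels (default 3).
#' @return A \linkS4class{StructureTensorField}.
#' @examples
#' img <- outer(seq(0, 1, length.out = 32), rep(1, 32))  # vertical ramp
#' f <- computeStructureTensor(img)
#' sum(f@tyy) > sum(f@txx)  # horizontal layering -> vertical gradients
#' @export
computeStructureTensor <- function(denoised, sigmaD = 1.0, sigmaW = 3.0) {
  D <- if (is(denoised, "RetinalScan")) grayChannel(denoised) else denoised
  if (length(dim(D)) != 2L) stop("grayscale input expected")
  if (sigmaD <= 0 || sigmaW <= 0) stop("Gaussian scales must be positive")
  g <- gaussianKernel1D(sigmaD, 0L)
  dg <- gaussianKernel1D(sigmaD, 1L)
  # separable Gaussian-derivative responses (x = columns, y = rows)
  phiX <- correlate2(D, outer(g, dg))
  phiY <- correlate2(D, outer(dg, g))
  gw <- gaussianKernel1D(sigmaW, 0L)
  W <- outer(gw, gw)
  txx <- correlate2(phiX^2, W)
  tyy <- correlate2(phiY^2, W)
  txy <- correlate2(phiX * phiY, W)
  # FFT filtering leaves tiny negative residue on flat regions
  txx[txx < 0] <- 0
  tyy[tyy < 0] <- 0
  new("StructureTensorField", txx = txx, tyy = tyy, txy = txy,
      sigmaD = sigmaD, sigmaW = sigmaW)
}

#' Eigenvalue coherence of a structure tensor field
#'
#' Per pixel, the eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge 0} of the
#' 2x2 tensor are obtained in closed form and the degree of coherency is
#' \deqn{c = \left(\frac{\lambda_1 - \lambda_2}
#'                      {\lambda_1 + \lambda_2}\right)^2,}
#' with \eqn{c = 0} where the trace vanishes. c is 1 for perfectly
#' line-like structure and 0 for isotropic neighbourhoods. Channel scores
#' summarise the mean coherence-weighted energy of each tensor channel and
#' indicate which channel carries the oriented structure.
#'
#' @param field a \linkS4class{StructureTensorField}.
#' @return A \linkS4class{CoherenceSummary}.
#' @export
coherence <- function(field) {
  stopifnot(is(field, "StructureTensorField"))
  tr <- field@txx + field@tyy
  disc <- sqrt(((field@txx - field@tyy) / 2)^2 + field@txy^2)
  cc <- matrix(0, nrow(tr), ncol(tr))
  nz <- tr > 0
  cc[nz] <- (2 * disc[nz] / tr[nz])^2
  cc <- pmin(cc, 1)
  scores <- c(txx = mean(cc * field@txx),
              tyy = mean(cc * field@tyy),
              txy = mean(cc * abs(field@txy)))
  new("CoherenceSummary", coherence = cc, channelScores = scores)
}

#' Select or fuse tensor channels per modality
#'
#' Retinal layers in OCT B-scans are horizontally oriented, so their
#' structure is carried by the vertically computed tensor: mode
#' \code{"oct_layers"} returns \code{tyy}. Fundus vessels run in every
#' direction, so mode \code{"fundus_vessels"} fuses the diagonal channels
#' into TMAX, the element-wise maximum of \code{txx} and \code{tyy}, which
#' preserves the strongest response of either orientation. The returned
#' grid is rescaled to [0, 1].
#'
#' @param field a \linkS4class{StructureTensorField}.
#' @param mode \code{"oct_layers"} or \code{"fundus_vessels"}.
#' @return A numeric response matrix in [0, 1].
#' @export
selectTensor <- function(field, mode = c("oct_layers", "fundus_vessels")) {
  stopifnot(is(field, "StructureTensorField"))
  mode <- match.arg(mode)
  r <- switch(mode,
              oct_layers = field@tyy,
              fundus_vessels = pmax(field@txx, field@tyy))
  rescale01(r)
}

#' Canny edge detection
#'
#' The canonical chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' linking. Thresholds are expressed as fractions of the maximum gradient
#' magnitude of the (smoothed) response grid.
#'
#' @param response numeric matrix, values in [0, 1].
#' @param low,high hysteresis thresholds with \code{0 <= low < high <= 1}.
#' @param sigma smoothing scale before differentiation (default 1.4).
#' @return A binary edge matrix.
#' @export
cannyEdges <- function(response, low = 0.1, high = 0.3, sigma = 1.4) {
  if (!is.matrix(response)) stop("response must be a matrix")
  if (low < 0 || high > 1 || low >= high)
    stop("need 0 <= low < high <= 1")
  g <- gaussianKernel1D(sigma, 0L)
  sm <- correlate2(response, outer(g, g))
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (cols)
  sy <- t(sx)                                               # d/dy (rows)
  gx <- correlate2(sm, sx)
  gy <- correlate2(sm, sy)
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  # an (effectively) constant grid has no edges; the floor also guards
  # against FFT residue on exact constants being normalized up to O(1)
  if (mx <= 1e-8) return(matrix(0, nrow(mag), ncol(mag)))
  mag <- mag / mx
  nr <- nrow(mag); nc <- ncol(mag)
  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  padM <- matrix(0, nr + 2L, nc + 2L)
  padM[2:(nr + 1L), 2:(nc + 1L)] <- mag
  ic <- 2:(nr + 1L); jc <- 2:(nc + 1L)
  off <- list(`0` = c(0L, 1L),   # horizontal gradient -> compare left/right
              `1` = c(1L, 1L),   # diagonal
              `2` = c(1L, 0L),   # vertical gradient -> compare up/down
              `3` = c(1L, -1L))
  keep <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    o <- off[[as.character(s)]]
    n1 <- padM[ic + o[1], jc + o[2]]
    n2 <- padM[ic - o[1], jc - o[2]]
    sel <- sector == s & mag >= n1 & mag >= n2
    keep[sel] <- TRUE
  }
  thin <- mag * keep
  hysteresisThreshold(thin, low, high)
}
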