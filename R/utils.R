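# Internal numerical helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' @importFrom stats runif rnorm median
NULL

# Rescale a matrix to [0, 1]; an all-constant input maps to zeros.
rescale01 <- function(m) {
  rng <- range(m)
  if (!all(is.finite(rng))) stop("non-finite values in grid")
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

# Symmetric (mirror) padding of a matrix by pr rows and pc columns.
padSymmetric <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  if (pr >= nr || pc >= nc) stop("padding exceeds image size")
  ri <- c(rev(seq_len(pr)), seq_len(nr), nr + 1 - seq_len(pr))
  ci <- c(rev(seq_len(pc)), seq_len(nc), nc + 1 - seq_len(pc))
  m[ri, ci, drop = FALSE]
}

# Local box sums over a wv x wh window (rows x cols) with symmetric padding,
# computed with summed-area tables so the result is exact up to rounding.
localBoxSum <- function(m, wv, wh) {
  rv <- (wv - 1L) %/% 2L
  rc <- (wh - 1L) %/% 2L
  p <- padSymmetric(m, rv, rc)
  I <- t(apply(apply(p, 2L, cumsum), 1L, cumsum))
  S <- rbind(0, cbind(0, I))
  i1 <- seq_len(nrow(m)); i2 <- i1 + wv
  j1 <- seq_len(ncol(m)); j2 <- j1 + wh
  S[i2, j2, drop = FALSE] - S[i1, j2, drop = FALSE] -
    S[i2, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
}

# Sampled Gaussian kernel (deriv = 0) or its first derivative (deriv = 1),
# truncated at 3 sigma. The smoothing kernel is normalised to unit sum.
gaussianKernel1D <- function(sigma, deriv = 0L) {
  if (sigma <= 0) stop("sigma must be positive")
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (deriv == 0L) g else -x / sigma^2 * g
}

# 2-D correlation with replicate boundary handling:
#   out[i, j] = sum_{a, b} K[a, b] * x[i + a - c, j + b - c]
# EBImage::filter2 convolves (flips the kernel), so flip here to get
# correlation semantics that match the literal double-loop definition.
correlate2 <- function(m, K) {
  Kf <- K[rev(seq_len(nrow(K))), rev(seq_len(ncol(K))), drop = FALSE]
  EBImage::filter2(m, Kf, boundary = "replicate")
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels touching diagonally are merged with a union-find pass.
labelComponents <- function(mask) {
  la <- EBImage::bwlabel(mask != 0)
  n <- max(la)
  if (n <= 1L) return(la)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unionPairs <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    for (k in which(keep)) {
      ra <- findRoot(a[k]); rb <- findRoot(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  nr <- nrow(la); nc <- ncol(la)
  unionPairs(la[-nr, -nc], la[-1L, -1L])   # down-right diagonal
  unionPairs(la[-nr, -1L], la[-1L, -nc])   # down-left diagonal
  roots <- vapply(seq_len(n), findRoot, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- la
  out[la > 0] <- relab[la[la > 0]]
  out
}

# Drop labelled components outside an area (or length) band; returns a
# binary matrix.
filterComponents <- function(labels, keepFun) {
  n <- max(labels)
  if (n == 0L) return(matrix(0, nrow(labels), ncol(labels)))
  keep <- vapply(seq_len(n), keepFun, logical(1))
  out <- matrix(0, nrow(labels), ncol(labels))
  out[labels > 0 & keep[pmax(labels, 1L)]] <- 1
  out
}

componentAreas <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0], nbins = n)
}

# Centered moving average tolerating NA; window shrinks at the ends.
movingAverageNA <- function(v, w) {
  if (w %% 2L != 1L || w < 1L) stop("window must be odd and positive")
  r <- (w - 1L) %/% 2L
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - r):min(n, i + r)
    out[i] <- mean(v[idx], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

# Hysteresis thresholding: keep weak-threshold components that contain at
# least one strong pixel (8-connected).
hysteresisThreshold <- function(mag, low, high) {
  if (low >= high) stop("'low' must be strictly below 'high'")
  weak <- mag >= low
  strong <- mag >= high
  if (!any(strong)) return(matrix(0, nrow(mag), ncol(mag)))
  la <- labelComponents(weak)
  keepLab <- unique(la[strong & la > 0])
  out <- matrix(0, nrow(mag), ncol(mag))
  out[la %in% keepLab & la > 0] <- 1
  out
}

# Binary disc mask stamped onto `mask` (in place semantics via return).
stampDisc <- function(mask, cy, cx, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  i1 <- max(1L, floor(cy - r)); i2 <- min(nr, ceiling(cy + r))
  j1 <- max(1L, floor(cx - r)); j2 <- min(nc, ceiling(cx + r))
  if (i1 > i2 || j1 > j2) return(mask)
  ii <- i1:i2; jj <- j1:j2
  d2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
  sub <- mask[ii, jj, drop = FALSE]
  sub[d2 <= r^2] <- 1
  mask[ii, jj] <- sub
  mask
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

isBinaryGrid <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}
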