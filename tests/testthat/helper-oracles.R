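# Independent brute-force oracles used to pin down the numerical core.
# These deliberately re-derive every quantity with literal double loops
# so they share no code path with the implementation.

# Adaptive Wiener filter evaluated pixel by pixel with mirror padding.
oracleWiener <- function(O, wv, wh, a2) {
  r <- (wv - 1) / 2; cc <- (wh - 1) / 2
  n <- nrow(O); m <- ncol(O)
  refl <- function(i, n) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    i
  }
  D <- O
  for (i in 1:n) for (j in 1:m) {
    v <- O[refl((i - r):(i + r), n), refl((j - cc):(j + cc), m)]
    mu <- mean(v)
    s2 <- mean(v^2) - mu^2
    D[i, j] <- if (s2 <= 0) mu else mu + max(s2 - a2, 0) / s2 * (O[i, j] - mu)
  }
  D
}

# Literal 2-D correlation; NA outside full-support pixels.
oracleCorrelate <- function(m, K) {
  rc <- (nrow(K) - 1) / 2; cc <- (ncol(K) - 1) / 2
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in (1 + rc):(nrow(m) - rc)) for (j in (1 + cc):(ncol(m) - cc))
    out[i, j] <- sum(K * m[(i - rc):(i + rc), (j - cc):(j + cc)])
  out
}

# Structure tensor via literal weighted sums of the derivative products.
oracleTensor <- function(img, sigmaD, sigmaW) {
  g <- retfuse:::gaussianKernel1D(sigmaD, 0L)
  dg <- retfuse:::gaussianKernel1D(sigmaD, 1L)
  gw <- retfuse:::gaussianKernel1D(sigmaW, 0L)
  phiX <- oracleCorrelate(img, outer(g, dg))
  phiY <- oracleCorrelate(img, outer(dg, g))
  W <- outer(gw, gw)
  list(txx = oracleCorrelate(phiX^2, W),
       tyy = oracleCorrelate(phiY^2, W),
       txy = oracleCorrelate(phiX * phiY, W),
       pad = (length(g) - 1) / 2 + (length(gw) - 1) / 2)
}

innerRegion <- function(m, pad) {
  m[(1 + pad):(nrow(m) - pad), (1 + pad):(ncol(m) - pad)]
}

# Gaussian naive Bayes posterior by direct evaluation of Bayes' rule.
oracleBayesPosterior <- function(x, mu, va, prior) {
  lik <- vapply(seq_along(prior), function(ci)
    prod(stats::dnorm(x, mu[ci, ], sqrt(va[ci, ]))) * prior[ci],
    numeric(1))
  lik / sum(lik)
}

rotate90 <- function(m) t(m)[, nrow(m):1]
unrotate90 <- function(m) t(m[, ncol(m):1])

# Mean absolute error of extracted boundary curves against phantom truth
# (each curve scored against its nearest truth curve).
layerMAE <- function(boundaries, truth) {
  mean(vapply(seq_len(nrow(boundaries)), function(q)
    min(vapply(seq_len(nrow(truth)), function(r)
      mean(abs(boundaries[q, ] - truth[r, ]), na.rm = TRUE), numeric(1))),
    numeric(1)))
}
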