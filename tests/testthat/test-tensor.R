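test_that("structure tensor matches the literal weighted-sum oracle", {
  set.seed(7)
  img <- matrix(runif(32 * 32), 32, 32)
  f <- computeStructureTensor(img, sigmaD = 1, sigmaW = 1.5)
  orc <- oracleTensor(img, 1, 1.5)
  pad <- orc$pad
  expect_lt(max(abs(innerRegion(f@txx - orc$txx, pad)), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(innerRegion(f@tyy - orc$tyy, pad)), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(innerRegion(f@txy - orc$txy, pad)), na.rm = TRUE), 1e-6)
})

test_that("tensor channels encode orientation as expected", {
  # constant image: all channels vanish
  f0 <- computeStructureTensor(matrix(0.5, 24, 24), 1, 2)
  expect_equal(max(abs(f0@txx)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f0@tyy)), 0, tolerance = 1e-12)

  # vertical step edge (intensity varies along x): txx dominates
  step <- cbind(matrix(0.2, 32, 16), matrix(0.8, 32, 16))
  fs <- computeStructureTensor(step, 1, 2)
  expect_gt(sum(fs@txx), sum(fs@tyy))

  # horizontally layered gradient (varies along y): tyy dominates
  layered <- outer(seq(0, 1, length.out = 32), rep(1, 32))
  fl <- computeStructureTensor(layered, 1, 2)
  expect_gt(sum(fl@tyy), sum(fl@txx))

  expect_error(computeStructureTensor(step, sigmaD = 0), "positive")
})

test_that("rotating the image by 90 degrees swaps the diagonal channels", {
  set.seed(3)
  img <- matrix(runif(28 * 28), 28, 28)
  f <- computeStructureTensor(img, 1, 2)
  fr <- computeStructureTensor(rotate90(img), 1, 2)
  expect_lt(max(abs(unrotate90(fr@txx) - f@tyy)), 1e-12)
  expect_lt(max(abs(unrotate90(fr@tyy) - f@txx)), 1e-12)
})

test_that("intensity scaling scales energies quadratically, coherence unchanged", {
  set.seed(5)
  img <- matrix(runif(24 * 24), 24, 24)
  f1 <- computeStructureTensor(img, 1, 2)
  f2 <- computeStructureTensor(img * 3, 1, 2)
  expect_equal(f2@txx, 9 * f1@txx, tolerance = 1e-10)
  expect_equal(f2@txy, 9 * f1@txy, tolerance = 1e-10)
  expect_equal(coherence(f2)@coherence, coherence(f1)@coherence,
               tolerance = 1e-9)
})

test_that("coherence matches the closed form and an eigensolver oracle", {
  iso <- new("StructureTensorField", txx = matrix(1, 2, 2),
             tyy = matrix(1, 2, 2), txy = matrix(0, 2, 2),
             sigmaD = 1, sigmaW = 1)
  expect_equal(coherence(iso)@coherence, matrix(0, 2, 2))
  rank1 <- new("StructureTensorField", txx = matrix(1, 2, 2),
               tyy = matrix(0, 2, 2), txy = matrix(0, 2, 2),
               sigmaD = 1, sigmaW = 1)
  expect_equal(coherence(rank1)@coherence, matrix(1, 2, 2))

  set.seed(9)
  img <- matrix(runif(16 * 16), 16, 16)
  f <- computeStructureTensor(img, 1, 1.5)
  cc <- coherence(f)@coherence
  for (idx in list(c(4, 5), c(8, 8), c(12, 3), c(15, 15))) {
    i <- idx[1]; j <- idx[2]
    M <- matrix(c(f@txx[i, j], f@txy[i, j], f@txy[i, j], f@tyy[i, j]), 2)
    ev <- eigen(M, symmetric = TRUE)$values
    want <- if (sum(ev) <= 0) 0 else ((ev[1] - ev[2]) / (ev[1] + ev[2]))^2
    expect_lt(abs(cc[i, j] - want), 1e-9)
  }
})

test_that("selectTensor returns tyy for OCT and TMAX for fundus", {
  ph <- mePhantomOCT()
  f <- computeStructureTensor(grayChannel(ph$scan), 1, 3)
  r <- selectTensor(f, "oct_layers")
  expect_equal(r, (f@tyy - min(f@tyy)) / (max(f@tyy) - min(f@tyy)))
  rf <- selectTensor(f, "fundus_vessels")
  mx <- pmax(f@txx, f@tyy)
  expect_equal(rf, (mx - min(mx)) / (max(mx) - min(mx)))
  expect_true(all(rf >= 0 & rf <= 1))

  zero <- new("StructureTensorField", txx = matrix(0, 3, 3),
              tyy = matrix(0, 3, 3), txy = matrix(0, 3, 3),
              sigmaD = 1, sigmaW = 1)
  expect_equal(selectTensor(zero, "oct_layers"), matrix(0, 3, 3))
  expect_error(selectTensor(f, "other"), "arg")
})

test_that("canny finds thin edges where they belong", {
  # constant grid: no edges
  expect_equal(sum(cannyEdges(matrix(0.5, 32, 32), 0.1, 0.3)), 0)

  # single ideal vertical step: one 1-pixel-wide edge line
  step <- cbind(matrix(0.1, 40, 20), matrix(0.9, 40, 20))
  e <- cannyEdges(step, 0.1, 0.3)
  inner <- e[5:36, ]
  expect_true(all(rowSums(inner) == 1))          # one pixel per row
  expect_equal(max(retfuse:::labelComponents(e)), 1)  # a single chain
  expect_true(all(which(colSums(inner) > 0) %in% 20:21))

  # flat layered image: one chain per band boundary
  bands <- rbind(matrix(0.1, 30, 80), matrix(0.5, 30, 80),
                 matrix(0.9, 30, 80))
  eb <- cannyEdges(bands, 0.1, 0.3)
  expect_equal(max(retfuse:::labelComponents(eb)), 2)

  expect_error(cannyEdges(step, 0.4, 0.2), "low")
})
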