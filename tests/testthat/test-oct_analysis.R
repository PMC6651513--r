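# Build the response/edge pair the way the pipeline wires the tensor
# stage into boundary tracing.
layerInputs <- function(img, cfg = retfuseConfig()) {
  f <- computeStructureTensor(img, cfg$tensor$sigmaD, cfg$tensor$sigmaW)
  list(response = selectTensor(f, "oct_layers"),
       edges = cannyEdges(img, cfg$octEdges$low, cfg$octEdges$high))
}

test_that("two flat boundaries are traced within one row", {
  img <- matrix(0.05, 400, 120)
  img[100:299, ] <- 0.55
  img <- retfuse:::gaussBlur2(img, 1.2)
  li <- layerInputs(img)
  ls <- extractLayers(li$response, li$edges, k = 2, J = 3,
                      intensity = img)
  B <- ls@boundaries
  expect_equal(nrow(B), 2L)
  expect_true(all(abs(B[1, ] - 99.5) <= 1))
  expect_true(all(abs(B[2, ] - 299.5) <= 1))
  expect_equal(ls@ilmIndex, 1L)
  expect_equal(ls@rpeIndex, 2L)
})

test_that("a nine-boundary phantom is recovered with small error", {
  ph <- generateOCTPhantom(phantomSpec("oct", "me", seed = 7))
  den <- preprocessScan(ph$scan, retfuseConfig())
  ex <- extractOCTFindings(den, retfuseConfig())
  B <- ex$layers@boundaries
  expect_lte(nrow(B), 9L)
  expect_gte(nrow(B), 8L)
  expect_lte(layerMAE(B, ph$truth$boundaries), 2)
  # ordering invariant: ILM above everything, RPE below everything
  ilm <- B[ex$layers@ilmIndex, ]; rpe <- B[ex$layers@rpeIndex, ]
  for (q in seq_len(nrow(B))) {
    ok <- !is.na(B[q, ]) & !is.na(ilm) & !is.na(rpe)
    expect_true(all(B[q, ok] >= ilm[ok] - 1e-9))
    expect_true(all(B[q, ok] <= rpe[ok] + 1e-9))
  }
  # continuity: no jump beyond the limit
  expect_true(all(abs(diff(t(B))) <= ex$layers@jumpLimit + 1e-9,
                  na.rm = TRUE))
})

test_that("an all-noise scan yields an extraction error", {
  set.seed(13)
  noise <- matrix(runif(200 * 150), 200, 150)
  li <- layerInputs(noise)
  expect_error(extractLayers(li$response, li$edges, k = 9, J = 3),
               "unusable")
})

test_that("fovea localization finds the deepest smoothed ILM point", {
  # parabolic pit with the vertex at column 256 (steep walls, as in a
  # real foveal depression)
  cols <- 1:512
  ilm <- 180 + 60 * pmax(0, 1 - ((cols - 256) / 25)^2)
  expect_equal(localizeFovea(ilm, 15), 256)

  # flat ILM: deterministic centre-most tie-break
  expect_equal(localizeFovea(rep(200, 512), 15), 256)

  # noisy parabola: seed 3, sigma = 2 px, window 15 -> within 2 columns
  set.seed(3)
  noisy <- ilm + rnorm(512, sd = 2)
  expect_lte(abs(localizeFovea(noisy, 15) - 256), 2)

  expect_error(localizeFovea(rep(NA_real_, 100), 15), "half")
})

test_that("the retinal mask spans strictly between ILM and RPE", {
  b <- rbind(rep(100, 50), rep(300, 50))
  ls <- new("LayerBoundarySet", boundaries = b, ilmIndex = 1L,
            rpeIndex = 2L, jumpLimit = 3)
  mask <- buildRetinalMask(ls, 400)
  expect_equal(colSums(mask), rep(199, 50))
  expect_true(all(mask[100, ] == 0) && all(mask[300, ] == 0))

  # ILM == RPE at a column: zero mask there
  b2 <- rbind(c(100, 150), c(100, 300))
  ls2 <- new("LayerBoundarySet", boundaries = b2, ilmIndex = 1L,
             rpeIndex = 2L, jumpLimit = 300)
  m2 <- buildRetinalMask(ls2, 400)
  expect_equal(sum(m2[, 1]), 0)
  expect_equal(sum(m2[, 2]), 149)
})

test_that("fluid extraction finds the seeded blobs and nothing outside the band", {
  cfg <- retfuseConfig()
  ph <- mePhantomOCT()     # 2 blobs, seed 5
  den <- preprocessScan(ph$scan, cfg)
  ex <- extractOCTFindings(den, cfg)
  fluid <- ex$masks@fluid
  expect_equal(max(retfuse:::labelComponents(fluid)), 2L)
  expect_gte(dice(fluid, ph$truth$fluid), 0.80)
  # fluid is a subset of the retinal band
  expect_true(all(fluid[ex$band == 0] == 0))

  # healthy phantom: empty mask
  ph0 <- healthyPhantomOCT()
  ex0 <- extractOCTFindings(preprocessScan(ph0$scan, cfg), cfg)
  expect_equal(sum(ex0$masks@fluid), 0)

  # a dark blob outside the band mask is not detected
  img <- pixels(den)
  img[20:40, 200:240] <- 0.01    # above the ILM, outside the band
  fl <- extractFluid(img, ex$band, cfg$fluid$t, cfg$fluid$minArea)
  expect_equal(sum(fl[20:40, 200:240]), 0)

  expect_error(extractFluid(img, matrix(0, nrow(img), ncol(img))),
               "empty")
})

test_that("the EDTRS 500-micrometer rule grades lesion proximity", {
  m <- emptyFindingMasks(100, 400)
  expect_equal(gradeClinicalSignificance(m, foveaCol = 200,
                                         umPerPixel = 10), "none")

  # exudate centroid 200 um from the fovea -> clinically significant
  m1 <- m; ex <- matrix(0, 100, 400); ex[50, 218:222] <- 1
  m1@exudates <- ex
  expect_equal(gradeClinicalSignificance(m1, 200, umPerPixel = 10),
               "clinically_significant")

  # nearest lesion at 600 um -> non-significant
  m2 <- m; fl <- matrix(0, 100, 400); fl[40, 260:262] <- 1
  m2@fluid <- fl
  expect_equal(gradeClinicalSignificance(m2, 200, umPerPixel = 10),
               "non_significant")

  # missing calibration with lesions present is an error
  expect_error(gradeClinicalSignificance(m1, 200), "calibration")
})
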