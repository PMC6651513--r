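test_that("softmax is normalized, shift-invariant and matches direct evaluation", {
  expect_equal(softmaxProb(c(0, 0)), c(0.5, 0.5))
  x <- c(1, 2, 3)
  direct <- exp(x) / sum(exp(x))
  expect_lt(max(abs(softmaxProb(x) - direct)), 1e-12)
  expect_equal(sum(softmaxProb(x)), 1, tolerance = 1e-9)
  # shift invariance (also at magnitudes that would overflow naively)
  expect_equal(softmaxProb(x + 123.4), softmaxProb(x), tolerance = 1e-12)
  expect_equal(softmaxProb(c(1000, 1001)), softmaxProb(c(0, 1)),
               tolerance = 1e-12)
  expect_error(softmaxProb(numeric(0)), "empty")
  expect_error(softmaxProb(c(1, Inf)), "finite")
})

test_that("the feature CNN has the published 14-layer geometry", {
  cfg <- featureCNNConfig()          # published raster: 227 x 227 x 3
  expect_length(cfg, 14L)
  expect_equal(cfg[[1]]$h, 227L)
  expect_equal(vapply(cfg, `[[`, character(1), "type"),
               c("input", "conv", "batchnorm", "relu", "maxpool",
                 "conv", "batchnorm", "relu", "dropout", "maxpool",
                 "conv", "batchnorm", "relu", "fc"))
  net <- buildFeatureCNN(cfg, seed = 1)
  # conv-1: 9x9x3 kernels, 8 filters -> 9*9*3*8 + 8 parameters
  expect_equal(cnnParameterCount(net, 2), 9 * 9 * 3 * 8 + 8)
  expect_equal(net$featDim, 8L)
  x <- array(runif(227 * 227 * 3), c(227, 227, 3, 1))
  expect_equal(dim(predictCNN(net, x, type = "features")), c(8L, 1L))
  expect_error(predictCNN(net, array(0, c(64, 64, 3, 1))), "shape")
})

test_that("the AlexNet-style recognizer geometry is preserved as documentation", {
  tab <- alexnetLayerTable()
  expect_equal(nrow(tab), 25L)
  expect_equal(sum(tab$func == "conv"), 5L)
  expect_equal(sum(grepl("4096", tab$description)), 2L)
  expect_equal(tab$description[25], "two classes (OCT, fundus)")
})

smallConfig <- function(s = 16L) list(
  list(type = "input", h = s, w = s, c = 3L, zerocenter = TRUE),
  list(type = "conv", filters = 4L, k = 3L, stride = 1L, pad = "same"),
  list(type = "batchnorm"),
  list(type = "relu"),
  list(type = "maxpool", k = 2L, stride = 2L),
  list(type = "fc", units = 6L))

test_that("CNN training is seeded, deterministic and stationary at lr = 0", {
  set.seed(42)
  x <- array(runif(16 * 16 * 3 * 12), c(16, 16, 3, 12))
  y <- rep(c("healthy", "me"), 6)
  m0 <- buildFeatureCNN(smallConfig(), seed = 4)
  m1 <- trainCNN(m0, x, y, epochs = 3, batchSize = 4, seed = 11)
  m2 <- trainCNN(m0, x, y, epochs = 3, batchSize = 4, seed = 11)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)

  # a zero learning rate leaves weights alone, so the loss over one
  # repeated full batch is constant across iterations
  mz <- trainCNN(m0, x, y, epochs = 3, batchSize = 12, lr = 0, seed = 2)
  expect_lt(diff(range(mz$log$loss)), 1e-9)

  expect_error(trainCNN(m0, x, rep("me", 12)), "two classes")
})

test_that("feature extraction is deterministic at inference", {
  set.seed(8)
  x <- array(runif(16 * 16 * 3 * 6), c(16, 16, 3, 6))
  m <- trainCNN(buildFeatureCNN(smallConfig(), seed = 1), x,
                rep(c("healthy", "me"), 3), epochs = 2, seed = 1)
  f1 <- predictCNN(m, x, type = "features")
  f2 <- predictCNN(m, x, type = "features")
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
})

test_that("modality recognition works on phantoms and replicates grayscale", {
  models <- miniModels()
  octScan <- healthyPhantomOCT()$scan
  funScan <- healthyPhantomFundus()$scan
  rOct <- recognizeModality(models$modality, octScan)
  rFun <- recognizeModality(models$modality, funScan)
  expect_equal(rOct$modality, "oct")
  expect_gt(rOct$probability, 0.5)
  expect_equal(rFun$modality, "fundus")
  # grayscale inputs are replicated to three channels before the CNN
  x <- prepareCNNInput(matrix(0.3, 60, 80), 16)
  expect_equal(dim(x), c(16L, 16L, 3L, 1L))
  expect_equal(x[, , 1, 1], x[, , 3, 1])
  expect_error(recognizeModality(buildFeatureCNN(smallConfig()), octScan),
               "trained")
})

test_that("overlays burn findings deterministically and leave the scan alone", {
  ph <- mePhantomOCT()
  cfg <- retfuseConfig()
  den <- preprocessScan(ph$scan, cfg)
  d <- dim(pixels(den))
  # empty masks: the scan is replicated to 3 channels, unchanged
  empty <- emptyFindingMasks(d[1], d[2])
  ov0 <- overlayFindings(den, empty)
  expect_equal(dim(pixels(ov0)), c(d, 3L))
  for (ch in 1:3) expect_equal(pixels(ov0)[, , ch], pixels(den))

  # fluid-only mask: exactly the fluid pixels are recolored
  m <- empty
  fl <- matrix(0, d[1], d[2]); fl[200:210, 100:120] <- 1
  m@fluid <- fl
  ov1 <- overlayFindings(den, m)
  sel <- fl > 0
  expect_true(all(pixels(ov1)[, , 1][sel] == 1))
  expect_true(all(pixels(ov1)[, , 2][sel] == 0))
  for (ch in 1:3)
    expect_equal(pixels(ov1)[, , ch][!sel], pixels(den)[!sel])

  # overlaying identical inputs twice is idempotent
  ov2 <- overlayFindings(ov1, m)
  expect_equal(pixels(ov2), pixels(ov1))

  expect_error(overlayFindings(den, emptyFindingMasks(10, 10)), "shape")
})

test_that("feature fusion keeps OCT first and fundus second", {
  fv <- fuseFeatures(1:8, 9:16)
  expect_equal(unname(features(fv)), as.numeric(1:16))
  expect_length(features(fv), 16L)
  ba <- fuseFeatures(9:16, 1:8)
  expect_false(isTRUE(all.equal(features(fv), features(ba))))
  expect_error(fuseFeatures(1:7, 9:16), "length 8")
})
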