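test_that("phantom specs validate their fields", {
  expect_error(phantomSpec("oct", "healthy", fluidBlobs = 2),
               "inconsistent")
  expect_error(phantomSpec("fundus", "healthy", exudateCount = 3),
               "inconsistent")
  expect_error(phantomSpec("oct", "me", fluidBlobs = 9), "0..4")
  expect_error(phantomSpec("oct", "me", speckle = 1.2), "speckle")
  expect_error(phantomSpec("oct", "me", rows = 10), "small")
})

test_that("phantom generation is bit-reproducible from the seed", {
  a <- generateOCTPhantom(phantomSpec("oct", "me", seed = 21))
  b <- generateOCTPhantom(phantomSpec("oct", "me", seed = 21))
  expect_identical(pixels(a$scan), pixels(b$scan))
  expect_identical(a$truth, b$truth)
  cdiff <- generateOCTPhantom(phantomSpec("oct", "me", seed = 22))
  expect_false(identical(pixels(a$scan), pixels(cdiff$scan)))

  fa <- generateFundusPhantom(phantomSpec("fundus", "me", seed = 21))
  fb <- generateFundusPhantom(phantomSpec("fundus", "me", seed = 21))
  expect_identical(pixels(fa$scan), pixels(fb$scan))
  expect_identical(fa$truth, fb$truth)
})

test_that("phantom truths honour the anatomy invariants for many seeds", {
  for (seed in 1:5) {
    oct <- generateOCTPhantom(phantomSpec("oct", "me", seed = seed))
    tr <- oct$truth
    expect_equal(nrow(tr$boundaries), 9L)
    # boundaries ordered top to bottom
    expect_true(all(diff(tr$boundaries[, 1]) >= 0))
    # fluid strictly inside the ILM-RPE band
    fl <- which(tr$fluid > 0, arr.ind = TRUE)
    if (nrow(fl)) {
      ilm <- tr$boundaries[tr$ilmIndex, fl[, 2]]
      rpe <- tr$boundaries[tr$rpeIndex, fl[, 2]]
      expect_true(all(fl[, 1] > ilm & fl[, 1] < rpe))
    }
    fun <- generateFundusPhantom(phantomSpec("fundus", "me", seed = seed))
    ft <- fun$truth
    expect_equal(sum(ft$exudates * ft$vessels), 0)
    disc <- retfuse:::stampDisc(matrix(0, nrow(ft$exudates),
                                       ncol(ft$exudates)),
                                ft$opticDisc["cy"], ft$opticDisc["cx"],
                                ft$opticDisc["r"])
    expect_equal(sum(ft$exudates * disc), 0)
    # the vessel tree emanates from the disc rim
    near <- retfuse:::stampDisc(matrix(0, nrow(disc), ncol(disc)),
                                ft$opticDisc["cy"], ft$opticDisc["cx"],
                                ft$opticDisc["r"] + 6)
    expect_gt(sum(ft$vessels * near), 0)
    # exudates cluster near the macula
    ex <- which(ft$exudates > 0, arr.ind = TRUE)
    if (nrow(ex)) {
      dmac <- sqrt((ex[, 1] - ft$macula["cy"])^2 +
                     (ex[, 2] - ft$macula["cx"])^2)
      expect_true(all(dmac <= 1.5 * 2 * ft$opticDisc["r"] + 10))
    }
  }
})

test_that("a healthy phantom has empty lesion truths and a requested blob count is honoured", {
  h <- generateOCTPhantom(phantomSpec("oct", "healthy", seed = 2))
  expect_equal(sum(h$truth$fluid), 0)
  me <- generateOCTPhantom(phantomSpec("oct", "me", fluidBlobs = 2,
                                       seed = 5))
  expect_equal(max(retfuse:::labelComponents(me$truth$fluid)), 2L)
})

test_that("cohorts have the requested prevalence, pairing and split", {
  co <- generateCohort(10, prevalence = 0.5, seed = 9)
  labels <- vapply(co$subjects, `[[`, character(1), "label")
  expect_equal(sum(labels == "me"), 5L)
  expect_equal(nrow(co$manifest), 20L)       # two scans per subject
  expect_equal(sum(co$manifest$modality == "oct"), 10L)
  # oct and fundus of one subject share the label
  for (s in co$subjects) {
    expect_equal(s$octTruth$label, s$label)
    expect_equal(s$fundusTruth$label, s$label)
  }
  expect_setequal(unique(co$manifest$split), c("train", "validation"))

  co2 <- generateCohort(10, prevalence = 0.5, seed = 9)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(pixels(co$subjects[[3]]$oct),
                   pixels(co2$subjects[[3]]$oct))
  co3 <- generateCohort(10, prevalence = 0.5, seed = 10)
  expect_false(identical(pixels(co$subjects[[1]]$oct),
                         pixels(co3$subjects[[1]]$oct)))
  expect_error(generateCohort(0), "at least 1")
})

test_that("a cohort written to disk reloads through the manifest", {
  dir <- withr::local_tempdir()
  co <- generateCohort(2, prevalence = 0.5, seed = 3, dir = dir)
  mf <- suppressMessages(loadManifest(file.path(dir, "manifest.csv"),
                                      checkFiles = TRUE))
  expect_equal(nrow(mf), 4L)
  back <- readScan(mf$path[mf$modality == "oct"][1])
  expect_lt(max(abs(pixels(back) - pixels(co$subjects[[1]]$oct))), 1 / 255)
  # truth masks round-trip exactly
  fl <- readScan(file.path(dir, "subj0001_fluid_truth.png"))
  expect_identical(unname(pixels(fl)), co$subjects[[1]]$octTruth$fluid * 1)
})

test_that("segmentation difficulty is monotone in the speckle level", {
  cfg <- retfuseConfig()
  levels <- c(0.05, 0.2, 0.45)
  meanDice <- vapply(levels, function(sp) {
    mean(vapply(c(31, 32), function(seed) {
      ph <- generateOCTPhantom(phantomSpec("oct", "me", speckle = sp,
                                           seed = seed))
      ex <- extractOCTFindings(preprocessScan(ph$scan, cfg), cfg)
      dice(ex$masks@fluid, ph$truth$fluid)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanDice) <= 1e-9))
})
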