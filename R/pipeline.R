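#' Extract all OCT findings from a preprocessed B-scan
#'
#' Runs the OCT branch of the extraction stage: structure tensor, layer
#' response (tyy), Canny edges, boundary tracing, fovea localization,
#' ILM-RPE mask and fluid segmentation.
#'
#' @param denoised preprocessed grayscale OCT \linkS4class{RetinalScan}.
#' @param config a \code{\link{retfuseConfig}}.
#' @return list(masks = \linkS4class{FindingMasks},
#'   layers = \linkS4class{LayerBoundarySet},
#'   response = layer response grid).
#' @export
extractOCTFindings <- function(denoised, config = retfuseConfig()) {
  g <- grayChannel(denoised)
  field <- computeStructureTensor(g, config$tensor$sigmaD,
                                  config$tensor$sigmaW)
  resp <- selectTensor(field, "oct_layers")
  # boundary candidates come from intensity edges: Canny localizes each
  # band transition as a single thin chain, whereas edges of the (already
  # ridge-like) tyy response would flank every boundary twice; the tensor
  # response still ranks the candidates during tracing
  edges <- cannyEdges(g, config$octEdges$low, config$octEdges$high)
  layers <- extractLayers(resp, edges, k = config$layers$k,
                          J = config$layers$jumpLimit,
                          smoothWindow = config$layers$smoothWindow,
                          intensity = g)
  fovea <- localizeFovea(layers, config$fovea$smoothWindow)
  band <- buildRetinalMask(layers, nrow(g))
  fluid <- if (any(band > 0))
    extractFluid(g, band, config$fluid$t, config$fluid$minArea)
  else matrix(0, nrow(g), ncol(g))
  masks <- new("FindingMasks", fluid = fluid,
               vessels = matrix(0, nrow(g), ncol(g)),
               exudates = matrix(0, nrow(g), ncol(g)),
               opticDisc = numeric(0), foveaCol = as.numeric(fovea))
  list(masks = masks, layers = layers, response = resp, band = band)
}

#' Extract all fundus findings from a preprocessed scan
#'
#' Runs the fundus branch: structure tensor on the working channel, TMAX
#' fusion, vessel hysteresis segmentation, optic-disc localization and
#' hard-exudate extraction.
#'
#' @param denoised preprocessed grayscale fundus scan.
#' @param config a \code{\link{retfuseConfig}}.
#' @return list(masks = \linkS4class{FindingMasks},
#'   response = TMAX grid).
#' @export
extractFundusFindings <- function(denoised, config = retfuseConfig()) {
  g <- grayChannel(denoised)
  field <- computeStructureTensor(g, config$tensor$sigmaD,
                                  config$tensor$sigmaW)
  resp <- selectTensor(field, "fundus_vessels")
  fov <- fieldOfViewMask(g)
  vessels <- extractVessels(resp, config$vessels$low, config$vessels$high,
                            config$vessels$minLength, fov = fov, gray = g,
                            darkGate = config$vessels$darkGate)
  disc <- localizeOpticDisc(g, config$disc$radius, config$disc$floor)
  exud <- extractExudates(g, vessels, disc,
                          tBright = config$exudates$tBright,
                          topHatRadius = config$exudates$topHatRadius,
                          minArea = config$exudates$minArea,
                          maxArea = config$exudates$maxArea,
                          discDilate = config$exudates$discDilate)
  masks <- new("FindingMasks", fluid = matrix(0, nrow(g), ncol(g)),
               vessels = vessels, exudates = exud,
               opticDisc = if (is.null(disc)) numeric(0) else disc,
               foveaCol = NA_real_)
  list(masks = masks, response = resp)
}

# Preprocess + extract + overlay one scan of known modality; shared by
# training and inference so features are computed identically.
annotateScan <- function(scan, config) {
  den <- preprocessScan(scan, config)
  if (scan@modality == "oct") {
    ex <- extractOCTFindings(den, config)
    list(overlay = overlayFindings(den, ex$masks, ex$layers),
         masks = ex$masks, layers = ex$layers, denoised = den)
  } else {
    ex <- extractFundusFindings(den, config)
    list(overlay = overlayFindings(den, ex$masks),
         masks = ex$masks, layers = NULL, denoised = den)
  }
}

#' Train every model of the pipeline on a synthetic cohort
#'
#' Trains (1) the modality recognizer on all training scans, (2) one
#' feature CNN per modality on the annotated (overlaid) training scans,
#' and (3) the hybrid ANN/SVM/NB ensemble on the fused 16-D features.
#' Everything is seeded and the extraction stage is shared with
#' inference.
#'
#' @param cohort a \code{"retfuseCohort"} from \code{\link{generateCohort}}.
#' @param config a \code{\link{retfuseConfig}}.
#' @param seed RNG seed for all trainings.
#' @param verbose print progress.
#' @return A list of class \code{"retfuseModels"}: modality, octFeatures,
#'   fundusFeatures (\code{"retfuseCNN"}), ensemble
#'   (\code{"retfuseEnsemble"}), config, and the training feature matrix.
#' @export
trainRetfuseModels <- function(cohort, config = retfuseConfig(),
                               seed = 1L, verbose = FALSE) {
  stopifnot(inherits(cohort, "retfuseCohort"))
  train <- Filter(function(s) s$split == "train", cohort$subjects)
  if (!length(train)) stop("cohort has no training split")
  size <- config$cnn$inputSize
  labels <- vapply(train, `[[`, character(1), "label")

  # annotate one subject at a time, keeping only the resized CNN inputs:
  # retaining full-resolution overlays for a whole cohort would dominate
  # memory
  xOct <- array(0, c(size, size, 3L, length(train)))
  xFun <- array(0, c(size, size, 3L, length(train)))
  for (i in seq_along(train)) {
    if (verbose) message("annotating ", train[[i]]$id)
    xOct[, , , i] <-
      prepareCNNInput(annotateScan(train[[i]]$oct, config)$overlay, size)
    xFun[, , , i] <-
      prepareCNNInput(annotateScan(train[[i]]$fundus, config)$overlay,
                      size)
    if (i %% 10L == 0L) gc(FALSE)
  }

  xMod <- prepareCNNInput(c(lapply(train, `[[`, "oct"),
                            lapply(train, `[[`, "fundus")), size)
  yMod <- rep(c("oct", "fundus"), each = length(train))
  modality <- buildFeatureCNN(featureCNNConfig(size), nClasses = 2L,
                              classes = c("oct", "fundus"), seed = seed)
  modality <- trainCNN(modality, xMod, yMod, epochs = 4L,
                       lr = config$cnn$lr, momentum = config$cnn$momentum,
                       batchSize = config$cnn$batchSize, seed = seed)
  gc(FALSE)
  octNet <- buildFeatureCNN(featureCNNConfig(size), seed = seed + 1L)
  octNet <- trainCNN(octNet, xOct, labels, epochs = config$cnn$epochs,
                     lr = config$cnn$lr, momentum = config$cnn$momentum,
                     batchSize = config$cnn$batchSize, seed = seed + 1L)
  gc(FALSE)
  funNet <- buildFeatureCNN(featureCNNConfig(size), seed = seed + 2L)
  funNet <- trainCNN(funNet, xFun, labels, epochs = config$cnn$epochs,
                     lr = config$cnn$lr, momentum = config$cnn$momentum,
                     batchSize = config$cnn$batchSize, seed = seed + 2L)
  gc(FALSE)

  fOct <- t(predictCNN(octNet, xOct, type = "features"))
  fFun <- t(predictCNN(funNet, xFun, type = "features"))
  feats <- cbind(fOct, fFun)
  colnames(feats) <- paste0("f", 1:16)
  ensemble <- trainEnsemble(feats, labels, config, seed = seed)

  trainAcc <- c(
    modality = mean(predictCNN(modality, xMod) == yMod),
    oct = mean(predictCNN(octNet, xOct) == labels),
    fundus = mean(predictCNN(funNet, xFun) == labels))
  structure(list(modality = modality, octFeatures = octNet,
                 fundusFeatures = funNet, ensemble = ensemble,
                 config = config, trainingFeatures = feats,
                 trainingLabels = labels, trainingAccuracy = trainAcc),
            class = "retfuseModels")
}

#' Run the five-stage pipeline on one paired subject
#'
#' Stage order: modality recognition of both inputs (exactly one OCT and
#' one fundus scan are required), preprocessing, finding extraction,
#' overlay, CNN feature extraction and fusion, and the majority-vote
#' diagnosis. When lateral calibration is available the report includes
#' the EDTRS clinical-significance grade (lesions within 500 um of the
#' fovea). If recognition contradicts the declared modalities the
#' declaration wins and a warning is logged.
#'
#' @param octScan,fundusScan \linkS4class{RetinalScan} objects or file
#'   paths; declared order is OCT first, fundus second.
#' @param models a \code{"retfuseModels"} bundle.
#' @param config a \code{\link{retfuseConfig}}; defaults to the bundle's.
#' @return A list of class \code{"retfuseReport"}: diagnosis
#'   (\linkS4class{RetinalDiagnosis}), featureVector, octMasks,
#'   fundusMasks, layers, grade, and modality recognition details.
#' @export
runEndToEnd <- function(octScan, fundusScan, models,
                        config = models$config) {
  stopifnot(inherits(models, "retfuseModels"))
  if (is.character(octScan)) octScan <- readScan(octScan)
  if (is.character(fundusScan)) fundusScan <- readScan(fundusScan)
  recOct <- recognizeModality(models$modality, octScan)
  recFun <- recognizeModality(models$modality, fundusScan)
  if (recOct$modality == recFun$modality)
    stop("expected one OCT and one fundus scan, recognized two '",
         recOct$modality, "' scans")
  if (recOct$modality != "oct")
    warning("declared OCT scan recognized as ", recOct$modality,
            "; trusting the declaration")
  if (modality(octScan) == "unknown") modality(octScan) <- "oct"
  if (modality(fundusScan) == "unknown") modality(fundusScan) <- "fundus"

  aOct <- annotateScan(octScan, config)
  aFun <- annotateScan(fundusScan, config)

  size <- config$cnn$inputSize
  fOct <- predictCNN(models$octFeatures,
                     prepareCNNInput(aOct$overlay, size),
                     type = "features")[, 1]
  fFun <- predictCNN(models$fundusFeatures,
                     prepareCNNInput(aFun$overlay, size),
                     type = "features")[, 1]
  fv <- fuseFeatures(fOct, fFun)
  diag <- predictEnsemble(models$ensemble$ann, models$ensemble$svm,
                          models$ensemble$nb, fv,
                          scaler = models$ensemble$scaler)

  umLat <- umPerPixel(octScan)["lateral"]
  grade <- if (is.na(umLat)) NA_character_
  else gradeClinicalSignificance(aOct$masks,
                                 foveaCol = aOct$masks@foveaCol,
                                 umPerPixel = umLat,
                                 radiusUm = config$grading$radiusUm)
  structure(list(diagnosis = diag, featureVector = fv,
                 octMasks = aOct$masks, fundusMasks = aFun$masks,
                 layers = aOct$layers, grade = grade,
                 recognition = list(oct = recOct, fundus = recFun)),
            class = "retfuseReport")
}

#' @export
print.retfuseReport <- function(x, ...) {
  cat("retfuse report\n")
  cat("  final label:", x$diagnosis@final, "\n")
  cat("  votes:", paste(names(x$diagnosis@votes), x$diagnosis@votes,
                        sep = "=", collapse = ", "), "\n")
  if (!is.na(x$grade)) cat("  EDTRS grade:", x$grade, "\n")
  invisible(x)
}

#' Evaluate the pipeline on a cohort's validation split
#'
#' Runs the full pipeline on every validation subject, aggregates
#' confusion counts (ME is the positive class), computes the diagnostic
#' metrics and, where ground truth is available, the dice coefficient of
#' every extracted mask.
#'
#' @param cohort a \code{"retfuseCohort"}.
#' @param models a \code{"retfuseModels"} bundle.
#' @param config configuration; defaults to the bundle's.
#' @param verbose print progress.
#' @return list(metrics, counts, diceTable, predictions).
#' @export
evaluateCohort <- function(cohort, models, config = models$config,
                           verbose = FALSE) {
  val <- Filter(function(s) s$split == "validation", cohort$subjects)
  if (!length(val)) stop("cohort has no validation split")
  counts <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  diceRows <- list()
  preds <- character(length(val))
  for (i in seq_along(val)) {
    s <- val[[i]]
    rep <- runEndToEnd(s$oct, s$fundus, models, config)
    pred <- rep$diagnosis@final
    preds[i] <- pred
    if (s$label == "me" && pred == "me") counts["TP"] <- counts["TP"] + 1
    else if (s$label == "healthy" && pred == "healthy")
      counts["TN"] <- counts["TN"] + 1
    else if (s$label == "healthy" && pred == "me")
      counts["FP"] <- counts["FP"] + 1
    else counts["FN"] <- counts["FN"] + 1
    B <- rep$layers@boundaries
    Bt <- s$octTruth$boundaries
    layerMAE <- mean(vapply(seq_len(nrow(B)), function(q)
      min(vapply(seq_len(nrow(Bt)), function(r)
        mean(abs(B[q, ] - Bt[r, ]), na.rm = TRUE), numeric(1))),
      numeric(1)))
    diceRows[[length(diceRows) + 1L]] <- data.frame(
      subject = s$id,
      finding = c("fluid", "vessels", "exudates"),
      dice = c(dice(rep$octMasks@fluid, s$octTruth$fluid),
               dice(rep$fundusMasks@vessels, s$fundusTruth$vessels),
               dice(rep$fundusMasks@exudates, s$fundusTruth$exudates)),
      layerMAE = layerMAE,
      foveaErr = abs(rep$octMasks@foveaCol - s$octTruth$foveaCol),
      stringsAsFactors = FALSE)
    if (verbose) message(s$id, ": ", s$label, " -> ", pred)
    if (i %% 10L == 0L) gc(FALSE)
  }
  metrics <- classificationMetrics(TP = counts[["TP"]],
                                   TN = counts[["TN"]],
                                   FP = counts[["FP"]],
                                   FN = counts[["FN"]])
  list(metrics = metrics, counts = as.list(counts),
       diceTable = do.call(rbind, diceRows), predictions = preds)
}
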