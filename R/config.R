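#' Pipeline configuration
#'
#' One nested list holding every tunable threshold of the pipeline, so a
#' deployment can be described by a single object (or YAML file). Values
#' are the package defaults discussed in the methods vignette; any subset
#' can be overridden through \code{...} using the same nesting, e.g.
#' \code{retfuseConfig(fluid = list(t = 0.4))}.
#'
#' @param ... named top-level sections whose entries override defaults.
#' @return A nested list of class \code{"retfuseConfig"}.
#' @examples
#' cfg <- retfuseConfig(fluid = list(minArea = 50))
#' cfg$fluid$minArea
#' @export
retfuseConfig <- function(...) {
  cfg <- list(
    preprocess = list(nRows = 50L, gradientThresh = 0.5, satLevel = 0.8,
                      wh = 5L, wv = 5L, noiseFloor = NULL),
    tensor = list(sigmaD = 1.0, sigmaW = 3.0),
    octEdges = list(low = 0.05, high = 0.15),
    layers = list(k = 9L, jumpLimit = 3L, smoothWindow = 15L),
    fovea = list(smoothWindow = 75L),
    fluid = list(t = 0.5, minArea = 30L),
    vessels = list(low = 0.04, high = 0.2, minLength = 12,
                   darkGate = 0.85),
    disc = list(radius = 40, floor = 0.6),
    exudates = list(tBright = 1.3, topHatRadius = 8, minArea = 5L,
                    maxArea = 2000L, discDilate = 1.5),
    grading = list(radiusUm = 500),
    cnn = list(inputSize = 48L, epochs = 30L, lr = 0.01, momentum = 0.9,
               batchSize = 16L),
    ann = list(hidden = c(12L, 9L), epochs = 400L, lr = 0.5),
    svm = list(kernel = "rbf", C = 1, gamma = 1 / 16,
               mlpScale = 1 / 16, mlpOffset = 0)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    for (k in names(over[[nm]])) {
      if (!k %in% names(cfg[[nm]]) && !identical(k, "noiseFloor"))
        stop("unknown config entry: ", nm, "$", k)
      cfg[[nm]][[k]] <- over[[nm]][[k]]
    }
  }
  structure(cfg, class = c("retfuseConfig", "list"))
}
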