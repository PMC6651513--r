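# Shared, lazily built fixtures. Heavy objects (phantoms, trained mini
# models) are produced once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

mePhantomOCT <- function() fixture("meOct", function()
  generateOCTPhantom(phantomSpec("oct", "me", fluidBlobs = 2, seed = 5)))

healthyPhantomOCT <- function() fixture("healthyOct", function()
  generateOCTPhantom(phantomSpec("oct", "healthy", seed = 11)))

mePhantomFundus <- function() fixture("meFun", function()
  generateFundusPhantom(phantomSpec("fundus", "me", seed = 9)))

healthyPhantomFundus <- function() fixture("healthyFun", function()
  generateFundusPhantom(phantomSpec("fundus", "healthy", seed = 2)))

# A small paired cohort plus models trained on it, shared by the
# modality-recognition and pipeline tests (training scale is reduced to
# keep the default test run fast; the acceptance suite trains at the
# cohort scale the package documents).
miniCohort <- function() fixture("miniCohort", function()
  generateCohort(12, 0.5, seed = 77))

miniModels <- function() fixture("miniModels", function()
  trainRetfuseModels(miniCohort(),
                     retfuseConfig(cnn = list(epochs = 10L)), seed = 1))
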