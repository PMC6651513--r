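Package: retfuse
Title: Fused Fundus and OCT Analysis for Objective Macular Edema Grading
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Implements an ensemble pipeline that grades macular edema from
        paired retinal imaging modalities. OCT B-scans and fundus photographs
        are denoised with an adaptive local Wiener filter, clinically
        significant findings (retinal layer boundaries, intraretinal fluid,
        blood vessels, hard exudates, the optic disc) are extracted with
        structure-tensor coherence analysis, a small convolutional network
        distills each annotated modality into eight features, and the fused
        16-dimensional descriptor is classified by a majority vote over an
        artificial neural network, a support vector machine and a Gaussian
        naive Bayes model. Seeded synthetic retinal phantoms with ground-truth
        masks make every stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, EBImage, kernlab, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, yaml, e1071
biocViews: ImageProcessing, Classification, Ophthalmology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'cnn.R'
    'config.R'
    'diagnosis.R'
    'features.R'
    'fundus_analysis.R'
    'oct_analysis.R'
    'pipeline.R'
    'preprocess.R'
    'retfuse-package.R'
    'scan_io.R'
    'synthetic.R'
    'tensor.R'
    'utils.R'
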