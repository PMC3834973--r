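Package: mrmar
Title: MR-Guided Metal Artifact Reduction for X-Ray CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces dental-implant streak artifacts in reconstructed CT
    slices using a co-registered MR image. Corrupted CT pixels are located
    by multi-level Otsu thresholding of the gray-level histogram and
    replaced with CT values drawn from donor positions whose MR intensity
    is most similar to the corrupted position, so that restored values come
    from real tissue rather than interpolation. Ships the validation
    apparatus used to study the method: a 2D parallel-beam projector with
    ramp-filtered back-projection, a head-phantom simulator that produces
    metal-corrupted acquisitions, the standard sinogram-domain
    linear-interpolation baseline, and an evaluation runner that scores
    all methods against artifact-free reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    RNifti,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'mrmar-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'projection.R'
    'baseline.R'
    'correction.R'
    'detection.R'
    'phantom.R'
    'evaluation.R'
    'io.R'
    'cli.R'
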