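Package: kvimpact
Title: Impact of Real-Time kV Imaging Dose on Lung SBRT Planning Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the absorbed dose from real-time stereoscopic/monoscopic
    kilovoltage tumour-monitoring imaging perturbs dose-volume planning constraints in
    lung stereotactic body radiotherapy (SBRT). Provides S4 containers for regular-grid
    dose and density fields, contour rasterization and margin expansion for target and
    planning organ-at-risk volumes, an exact voxel-counting dose-volume-histogram engine
    (Dmean, Dmax to 0.03 cc, D2%, VD in cc and percent, PTV coverage), the RTOG 0915,
    LUSTER and SUNSET constraint tables with pass/fail bookkeeping under treatment and
    treatment-plus-imaging dose, a gantry-blocking stereoscopic/monoscopic imaging
    schedule model with an analytic primary-beam kV dose surrogate, a seeded synthetic
    thorax-cohort generator, and cohort-level reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'grids.R'
    'imaging.R'
    'structures.R'
    'dvh.R'
    'protocols.R'
    'phantom.R'
    'cohort.R'
    'bundle.R'
    'kvimpact-package.R'
    'reporting.R'
    'pipeline.R'
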