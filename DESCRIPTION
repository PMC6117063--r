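Package: psegrowth
Title: Growth Decomposition of Pseudostratified Neuroepithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative decomposition of isotropic growth in the zebrafish
    retinal pseudostratified epithelium (PSE) into its cell-level
    contributions. Provides logarithmic growth-rate balance analysis of
    morphometric measurement tables, a mean-field progenitor
    division/differentiation model, a mitotic-frustum apical-constraint
    ("proliferative trap") test, equal-area azimuthal density mapping of
    apical mitoses, apicobasal actin/nuclear intensity profiling with
    basal-zone detection, and a line-tension/surface-tension truncated-cone
    cell-shape model. A calibrated synthetic-retina generator emulates the
    statistical structure of the microscopy-derived measurements so the whole
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
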