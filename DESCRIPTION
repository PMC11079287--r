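Package: wsigrid
Title: Aggregation-Free Grid-Level Evaluation of Whole-Slide-Image Cancer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate computer-aided cancer detection on whole slide
    images at the level of physical square grids rather than aggregated slide
    scores. Provides grid meshing from pixel geometry and microns-per-pixel,
    conversion of binary segmentation masks to per-grid labels under a
    cumulative-area threshold, three-source ground-truth adjudication with
    chief-pathologist escalation, confusion counting at grid and slide
    granularity with Wald confidence intervals and diagnostic likelihood
    ratios, trapezoidal ROC/AUC, paired reader-revision analysis with
    McNemar tests and missed-slide Venn overlaps, and a synthetic cohort
    simulator (lesions, detection oracle, readers) so the whole pipeline is
    testable without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff
Config/testthat/edition: 3
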