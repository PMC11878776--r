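Package: hiwsi
Title: Hierarchical Multi-Scale Weakly Supervised Classification of
    Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the four endometrial-cancer molecular
    subtypes (MMRd, NSMP, p53abn, POLE mut) from hematoxylin-and-eosin
    whole-slide images.  Implements tumor-tile extraction with an RGB
    median background filter and a strict majority tumor-fraction rule,
    a three-scale patch hierarchy (full-tile, center-crop and
    selectively sampled quadrant views of each 1024-pixel tile), a
    multi-branch encoder with ratio-based partial freezing and a GELU
    fusion head, weakly supervised training with class-balanced patch
    resampling, soft-voting slide aggregation, and patient-grouped
    five-fold cross-validation with class-wise and macro AUROC
    reporting.  A deterministic synthetic-cohort generator emulates the
    multi-scale class structure the pipeline assumes, so the whole
    pipeline is testable without access to clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
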