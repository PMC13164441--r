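Package: nccthist
Title: Time-Histogram Metrics for Acute Ischemic Stroke Lesions on Non-Contrast CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies acute ischemic stroke lesions on non-contrast CT with
    first-order Hounsfield-unit histogram metrics (standard deviation, skewness,
    excess kurtosis, and Shannon entropy of a standardized 100-bin histogram over
    -40..60 HU), using contralateral mirrored regions of interest as within-subject
    controls. Provides ROI tools on HU arrays (extraction, midline estimation,
    mask mirroring, minimum-area rule), temporal trajectory analysis (percent HU
    decrease, lesion-control HU gap, crossover detection, sliding-window search
    for the peak diagnostic window), the group-comparison battery (one-way ANOVA,
    pooled t-tests with Bonferroni correction, Cohen's d, bootstrap confidence
    intervals, repeated-measures ANOVA), and a fully synthetic cohort generator
    whose pixel distributions are calibrated by nested bisection to prescribed
    SD/entropy targets, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
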