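Package: iphquant
Title: Muscle-Referenced Quantification of Carotid Intraplaque Hemorrhage on
    T1-Weighted MR Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying carotid intraplaque hemorrhage (IPH) on
    MPRAGE-like magnetic resonance volumes. Implements semi-automatic IPH
    segmentation by intensity thresholds expressed relative to the mean signal
    of a sternocleidomastoid muscle reference region (150%, 175%, 200%
    criteria) with a two-consecutive-slice minimal-extent rule, a two-phase
    region-based level-set segmenter serving as a manual-segmentation proxy,
    and agreement statistics between segmentation methods: intraclass
    correlation coefficients with confidence intervals, a six-band
    interpretation scale, Fisher z comparison of ICCs, and Bonferroni
    adjustment. A synthetic phantom generator produces vessel-wall/plaque/IPH
    volumes with known ground truth and Rician noise so the whole pipeline can
    be exercised and validated in silico.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
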