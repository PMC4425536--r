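Package: amplicall
Title: Poisson Error-Model Mutation Calling for RAS/BRAF Hotspot Amplicon Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects low-frequency hotspot mutations in KRAS, NRAS and BRAF
    from per-position allele-count tables produced by amplicon deep
    sequencing. Per-position background error rates are calibrated from a
    cohort of normal samples; systematically noisy positions are excluded;
    mutation-positive status is decided by an upper-tail Poisson test whose
    null expectation is (mean error rate + k standard deviations) times the
    sequencing depth. Includes a labelled-sample sweep for choosing the
    standard-deviation multiplier, a simulation-based limit-of-detection
    estimator, inter-assay concordance statistics (percent agreement,
    Cohen's kappa, discordance rates, paired tumor/plasma summaries), and a
    synthetic allele-count generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    seqinr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
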