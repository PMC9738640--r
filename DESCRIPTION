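Package: sewss
Title: Ischaemia Severity Scoring and Outcome Validation for Diabetic Foot Wounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the Ischaemia Severity Scale (ISS) for diabetic foot
    wounds, assigned from non-invasive vascular tests (pedal pulse palpation,
    ankle/brachial index, toe/brachial index, Doppler waveform category), and
    the Saint Elian Wound Score System (SEWSS) sum and grade bands.  Provides
    the validation toolkit used to assess such ordinal severity scales:
    Cohen's kappa inter-rater agreement, rate tables, odds ratios with Woolf
    confidence intervals, the Mantel-Haenszel chi-square test for linear
    trend, Kruskal-Wallis comparisons, and time-to-healing analysis
    (Kaplan-Meier curves, the k-group log-rank test, and a Cox
    proportional-hazards fit).  A seeded synthetic-cohort generator emulates
    the per-level measurement distributions and outcome rates of the original
    validation cohort so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
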