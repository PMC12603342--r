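Package: odorunits
Title: Single-Unit Spike-Train Statistics for Odor-Related Word Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for human medial-temporal-lobe single-unit
    recordings from a continuous word-recognition paradigm with odor-related
    and control words. Converts spike-time and trial-event tables into
    baseline-normalized window firing rates, screens units for stimulus
    responsiveness and odor association with Bonferroni or Benjamini-Hochberg
    control, tests per-region prevalence of flagged units with exact binomial
    tests, runs split-plot mixed ANOVAs of z-scored rates with LSD post-hoc
    comparisons, and performs cluster-based permutation tests on time-resolved
    firing rates. Includes a seeded inhomogeneous-Poisson session simulator
    with known ground truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
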