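Package: dyadsync
Title: Inter-Brain Synchrony Analysis for Dual-EEG Hyperscanning
Version: 0.1.0
Authors@R:
    person("dyadsync", "maintainers", email = "dyadsync@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of two-person (hyperscanning) EEG
    recordings: band-pass filtering, overlapping 1-s epoching, automatic
    peak-to-peak epoch rejection, template-correlation removal of ocular
    independent components, dyad epoch matching, theta-band weighted phase
    lag index (wPLI) and phase locking value (PLV) inter-brain connectivity
    over an adult-by-infant electrode grid, mass-univariate repeated-measures
    ANOVA with max-F permutation control of the family-wise error rate,
    pseudo-dyad surrogate nulls, normalized change scores with 3-SD outlier
    exclusion, microcoded behavior proportions, and a synthetic dyad
    generator with known ground-truth coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
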