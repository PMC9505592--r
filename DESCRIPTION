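Package: rdsmeta
Title: Case-Control Meta-Analysis and Risk Scoring of Reward-Pathway Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating candidate risk alleles of reward-pathway genes
    against collections of case-control association studies. Provides per-study
    odds ratios with confidence intervals, Hardy-Weinberg equilibrium testing,
    fixed-effects (inverse-variance and Mantel-Haenszel) and random-effects
    (DerSimonian-Laird) pooling, Cochran's Q and I-squared heterogeneity
    statistics, Hedges-Pigott power approximation, Egger regression and Begg
    rank-correlation publication-bias tests, Duval-Tweedie trim-and-fill
    adjustment, pre-test to post-test risk conversion, and multi-allele panel
    scoring, together with a synthetic study-collection generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
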