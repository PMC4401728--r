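Package: aglsdt
Title: Artificial Grammar Learning Designs, Simulated Observers, and
    Signal Detection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for artificial grammar learning (AGL) experiments that
    contrast nested (context-free) and cross-serial (mildly
    context-sensitive) dependencies over a fixed syllable lexicon.
    Generates counterbalanced learning and test trial lists, including
    strategy-control foil subsets that detect first- and
    last-element-pair shortcut strategies; simulates participant cohorts
    under equal-variance Gaussian signal-detection, deterministic
    single-pair strategist, and yes-biased guessing response policies;
    and runs the full analysis battery: log-linear corrected d-prime
    (overall, per block, per sequence length, and strategy-restricted),
    one-sample and independent-samples t tests with Cohen's d, mixed
    repeated-measures ANOVA with Greenhouse-Geisser correction and
    partial eta squared, and exact per-participant binomial strategy
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
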