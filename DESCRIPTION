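Package: iplgaze
Title: Analysis Pipeline for Infant Preferential-Looking Eye-Tracking Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-picture infant preferential-looking (IPL) word
    comprehension experiments: reading screen eye-tracker gaze exports,
    mapping gaze to areas of interest, participant- and trial-level
    exclusion screening, paired difference-in-looking-proportion scores,
    cluster-based permutation tests on binned target-looking time courses,
    and an inferential battery (Wilcoxon signed-rank tests with JZS Bayes
    factors, mixed-effects age-trajectory models, design-stage power and
    stimulus checks). Includes a synthetic gaze-cohort generator with
    known injected naming effects so the full chain is testable without
    infant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
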