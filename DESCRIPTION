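Package: txpassport
Title: Transcriptomic Athlete Biological Passport for Blood-Doping Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating whole-blood transcriptional markers of
    microdose recombinant human erythropoietin (rHuEpo) use within the
    Athlete Biological Passport framework. Implements reference-gene
    geometric-mean normalisation of bead-panel fluorescence data,
    within-subject longitudinal differential expression with empirical-Bayes
    variance moderation and a staged FDR/fold-change marker-selection
    cascade, haematological stimulation indices (OFF-score) with
    Holm-adjusted paired comparisons, and the adaptive Bayesian passport
    model that turns per-marker within- and between-subject variance
    components into individualised sequential reference ranges, atypical
    value flags, leave-one-out sensitivity/specificity and ROC areas. A
    synthetic-data module emulates the randomised placebo-controlled
    crossover microdose trial (14 subjects, 2 arms, 13 weekly time points,
    45 target and 5 reference probes) so the entire pipeline runs and is
    testable without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
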