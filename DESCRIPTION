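Package: degrank
Title: Evaluation of Gene Ranking Methods for Differential Expression
Version: 0.1.0
Authors@R:
    person("MAQC", "Bench", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements eight two-class gene ranking statistics (weighted
    average difference, average difference, fold change, rank products, and
    four moderated t variants), reference-based truth definitions from
    low-noise RT-PCR-style assays, evaluation metrics for sensitivity and
    specificity (AUC) and reproducibility (percentage of overlapping genes,
    Spearman rank correlation, average-linkage clustering of ranked lists),
    and a rank-average gene-set enrichment score with an intersection-union
    ratio for cross-platform gene-set agreement.  A synthetic data generator
    emulating the MAQC titration design (four sample types with C and D as
    3:1 and 1:3 mixtures of reference samples A and B, replicated across
    test sites and platforms) drives an end-to-end benchmarking pipeline
    with reproducible seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
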