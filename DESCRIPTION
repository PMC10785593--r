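Package: rgstab
Title: Reference-Gene Stability Analysis for qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects stable reference genes (RGs) for qRT-PCR normalization of
    miRNA expression. Preselects candidate RGs from small-RNA sequencing count
    matrices by abundance and coefficient of variation, scores candidates on Ct
    tables with four stability algorithms (geNorm M value and pairwise
    variation, NormFinder model-based stability, BestKeeper dispersion and
    index correlation, comparative Delta Ct), aggregates them into a consensus
    ranking by the geometric mean of ranks, decides the optimal number of RGs,
    and evaluates multi-gene normalizer combinations built as per-sample
    geometric means of Ct values. Includes a seeded generator of grouped qPCR
    Ct tables and negative-binomial count matrices emulating wound-healing and
    post-mortem study designs, and a config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
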