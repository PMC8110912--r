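Package: clonotrace
Title: Clonality, Diversity and Overlap Analysis of TCR-Beta Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of T-cell receptor beta-chain (TCR-beta) clonotype
    repertoires from bulk CDR3 sequencing: per-sample clonality (unique CDR3
    counts), the two-branch D50 diversity index, clonal-space homeostasis
    rank-bin profiles, exact CDR3 amino-acid overlap between repertoires with
    a read-normalised overlap index, TRBV/TRBJ gene-usage matrices with
    principal component analysis and per-gene group comparisons, cross-site
    ranking of expanded clones with Spearman correlation, and a synthetic
    cohort generator that emulates a paired lymph-node/joint study design
    with configurable clone-size mixtures, gene-usage profiles and designed
    cross-site sequence sharing. Reads and writes AIRR Rearrangement and
    MiXCR-style clone tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    seqinr,
    car,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
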