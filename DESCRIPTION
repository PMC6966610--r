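Package: jakstatmeta
Title: Meta-Analysis of JAK/STAT Pathway Lesions in T-Cell Prolymphocytic Leukemia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes somatic mutation, assay-coverage, copy-number, clinical
    and expression data from overlapping T-cell prolymphocytic leukemia (T-PLL)
    study cohorts into a unique-case registry and computes coverage-aware
    mutation frequencies, exon-level hotspot windows, protein-domain
    distributions, variant-allele-fraction (clonality) summaries, regulator
    copy-number lesion calls with per-case pathway-activation classification,
    and a clinical/expression association screen. Ships a deterministic
    synthetic cohort generator with ground-truth manifests for end-to-end
    validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, SomaticMutation, CopyNumberVariation, Survival, GeneExpression
RoxygenNote: 7.3.3
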