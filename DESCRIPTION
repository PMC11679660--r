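Package: hervtriage
Title: Targeted Variant Triage in Endogenous Retroviral Regions near Cancer Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control triage of common and rare variants inside human
    endogenous retrovirus (HERV) and Alu intervals located within a configurable
    radius of differentially expressed cancer predisposition genes. Provides
    interval selection and positional classification of retroviral elements,
    cohort VCF merging with missing-to-reference semantics and multiallelic
    splitting, supervised admixture estimation from ancestry-informative
    markers by an EM algorithm, per-variant unadjusted and covariate-adjusted
    logistic association with a confounding-change statistic, a multi-stage
    exclusion cascade with cross-database frequency consistency screens, a
    rare-variant enrichment and somatic-candidate screen with genotype-r2
    linkage clustering, and Alu poly(A)-tail run-length analysis of variant
    effects. A synthetic-data module generates every input the pipeline
    consumes, with known ground truth, in standard formats (VCF, BED, TSV,
    FASTA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
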