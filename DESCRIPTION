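Package: cnvrisk
Title: Germline Copy-Number Variant Discovery and Case-Control Risk Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case-control analysis pipeline for germline copy-number
    variants (CNVs) discovered from SNP-array intensity data. Provides
    dual-decoder hidden Markov model CNV calling from log R ratio (LRR) and
    B allele frequency (BAF) signals with GC-wave correction and
    distance-dependent transitions, stringent sample- and call-level quality
    control with dual-caller consensus merging, clustering of calls into CNV
    regions (CNVRs) by mutual overlap, per-individual CNV burden regression
    with technical-factor screening, in silico CNVR genotyping by constrained
    Gaussian mixtures with a joint mixture-logit likelihood-ratio risk test,
    and SNP-level cohort statistics (Hardy-Weinberg exact test, genotype PCA,
    Fisher's exact tests). Includes a synthetic cohort generator that emulates
    the statistical structure of hospital-based case-control SNP-array
    studies, with planted ground-truth CNVs for caller evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
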