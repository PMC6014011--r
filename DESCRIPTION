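Package: sfpevol
Title: Quantitative Evolutionary Proteomics of Primate Seminal Fluid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how mating systems shape the
    evolution of seminal fluid proteins. Normalizes label-free peptide
    quantifications (relative isotope abundances) by spiked internal
    standards, applies coefficient-of-variation quality control, rolls
    peptides up to proteins and computes normalized spectral abundance
    factors; compares abundances between species and between uni-male and
    multi-male mating systems with Wilcoxon rank-sum scans; detects positive
    selection in coding sequences with Goldman-Yang codon site models
    (M0/M1a/M2a/M7/M8/M8a) and the branch-site test with multi-male
    foreground lineages, with Storey q-value FDR control; estimates
    correlations between lineage-specific dN/dS and sexual characters with a
    multivariate Brownian-motion Gibbs sampler; and integrates all evidence
    into a candidate-gene table. A synthetic-data module generates every
    input the pipeline consumes so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
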