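Package: hetspan
Title: Genomic Heterozygosity and Healthy Aging Cohort Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing genomic heterozygosity between two
    genetically matched cohorts of biallelic autosomal SNP hard calls. Provides
    per-SNP excess-of-heterozygosity statistics, Hardy-Weinberg exact testing and
    LD-aware variant QC, PCA-based greedy genetic matching with genomic-inflation
    diagnostics, genotype-ratio and allelic association scans with exact binomial
    count-asymmetry meta-tests, pseudo-individual permutation nulls for the
    individual heterozygosity rate, Charlson 10-year survival modelling against
    EHR-like records, and top-decile hypergeometric gene-set enrichment. A
    synthetic two-cohort genotype generator with configurable heterozygote excess,
    Balding-Nichols ancestry structure, annotations and linked EHR records makes
    every stage testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
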