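Package: cismr
Title: Drug-Target Mendelian Randomisation with Correlated cis Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for cis (drug-target) Mendelian randomisation from GWAS
    summary statistics. Implements generalised-least-squares inverse-variance
    weighted and Egger estimators that model linkage disequilibrium between
    variants at a locus, greedy LD clumping with grid searches over clumping
    thresholds and region sizes, heterogeneity and leverage diagnostics with
    iterative outlier removal, sequential pruning of variants associated with
    non-target genes, and a simulation engine for the gene - protein -
    biomarker - disease causal model that produces LD-structured genotypes
    and two-sample marginal summary statistics with known estimands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
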