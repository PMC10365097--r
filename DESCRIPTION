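Package: fedchow
Title: Federated Chow Tests for Genotype-Stratified Expression-Imaging Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects genes whose expression-imaging-biomarker relationship differs
    across genotype-defined subgroups using a generalized (up to three-group) Chow
    structural-break F test, fitted under a federated protocol in which sites exchange
    only gradients, residual sums and counts with a coordinator. Includes a
    genome-scale trio scan (stratifier x gene x biomarker) with Benjamini-Hochberg
    correction and per-subgroup Pearson reporting, hypergeometric gene-set enrichment
    for ranking stratifying SNPs, an exact Hardy-Weinberg equilibrium filter,
    readers/writers for VCF/TSV genotype, expression and phenotype tables, and a
    seed-deterministic synthetic-data generator emulating genotype-stratified
    expression-biomarker structure across multiple hypothetical institutions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
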