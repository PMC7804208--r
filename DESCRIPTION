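Package: snpdx
Title: SNP-Genotype Diagnostic Models via Optimal Binary Coding and
    Naive Bayes Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds case/control diagnostic models from SNP genotype data.
    Each SNP (with missing calls kept as an explicit extra genotype state)
    is recoded into the binary variable whose category bipartition maximises
    the Pearson chi-square statistic against the phenotype; an iterated
    divide-and-conquer variant of the MMPC (max-min parents-and-children)
    algorithm reduces the binary features to a small candidate superset; a
    greedy forward/backward wrapper selects features for a naive Bayes
    classifier by cross-validated log-posterior score, in a best-scorer and
    a second-best-scorer variant; the two resulting models act as a pair of
    experts whose doubtful or incorrect diagnoses can be remedied by each
    other. Includes conditional-independence association scans, evaluation
    by leave-one-out and repeated stratified k-fold cross-validation, and a
    synthetic case/control genotype simulator with planted causal SNPs,
    linkage proxies and missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
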