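Package: mcsnpblup
Title: Monte Carlo SNP-BLUP Approximation of Genomic Reliabilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Approximates individual-animal genomic reliabilities with a
    fully Monte Carlo sampled SNP-BLUP model, alongside the exact GBLUP
    and exact SNP-BLUP-with-residual-polygenic-effect models it
    approximates. Includes pedigree relationship-matrix machinery
    (tabular method, Meuwissen-Luo inbreeding, Cholesky factors),
    VanRaden genomic relationship matrices, a gene-dropping simulator
    for synthetic pedigree/genotype/phenotype data, and comparison
    statistics (correlation, maximum difference, mean squared error,
    inflation regression) between exact and approximate reliabilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
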