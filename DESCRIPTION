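Package: grmforge
Title: Additive and Dominance Genomic Relationship Matrices Without
    Hardy-Weinberg Assumptions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction, diagnosis and comparison of additive (G) and
    dominance (D) genomic relationship matrices for GBLUP under arbitrary
    genotype frequencies. Implements six centering/scaling
    parameterizations (classical Hardy-Weinberg, non-HWE biological
    scales, NOIA, and three Gram-Schmidt orthogonalizations GSP-A, GSP-D
    and GSP-N), a vector-space angle diagnostic for additive-dominance
    orthogonality, an exact Hardy-Weinberg test, Kullback-Leibler
    divergence between relationship matrices, REML estimation of
    additive and dominance variance components, and a genotype/phenotype
    simulator with controllable heterozygote excess.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
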