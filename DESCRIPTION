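Package: ancientborder
Title: Detection of Ancient Genetic Borders from Uniparental Haplogroup Clines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting spatial genetic borders from the geographic
    distribution of mitochondrial and Y-chromosomal haplogroups. Implements
    haplogroup clustering into hunter-gatherer and farmer ancestry components,
    haplotype and nucleotide diversity estimators (Nei's unbiased estimator
    with analytic standard deviations), two-level AMOVA with permutation
    tests for pairwise F_ST and Phi_ST, an exhaustive scan over geographically
    contiguous bipartitions of a subpopulation adjacency graph scored by the
    product of binomial-GLM p-values with a randomized non-contiguous null,
    per-haplogroup regional bias estimation, bias-versus-haplogroup-age rank
    correlation, and a fully reproducible synthetic-data generator that plants
    a known border for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
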