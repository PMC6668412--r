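Package: leikit
Title: Allele-Frequency Based Selection of Ancestry Informative Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks single-nucleotide polymorphisms by their ability to
    distinguish ancestral populations, using the Lancaster estimator of
    independence computed either from individual-level genotypes or from
    summary-level population allele frequencies under Hardy-Weinberg
    equilibrium. Includes baseline machine-learning rankers (principal
    component loadings, random-forest Gini importance, linear support
    vector machine weights), global FST scoring, simulators for two-way
    Poisson-switch and three-way block-mosaic admixed cohorts with full
    ancestry bookkeeping, supervised maximum-likelihood estimation of
    global ancestry proportions, and evaluation utilities
    (leave-one-out multinomial classification, multiclass AUC, top-N
    ranking overlap, root mean square error of ancestry estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    randomForest,
    e1071,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
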