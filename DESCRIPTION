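Package: dispersalscreen
Title: Genomic Screening for Dispersal Histories in Long-Lived Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A population-genomic screening workflow for identifying
    long-lived non-crop plant species whose genetic patterns are consistent
    with propagule dispersal following long-term isolation, as expected
    under precolonial human-mediated translocation, and for screening out
    species whose patterns are explained by ongoing faunal dispersal or
    pure isolation. Provides multilocus pairwise Fst (Weir-type
    ratio-of-averages estimator), distance-binned Fst summaries, Mantel
    isolation-by-distance tests, sparse-NMF-style admixture inference with
    cross-entropy model selection, principal components analysis of
    genotypes, chloroplast haplotype networks with median-node inference,
    a four-signal decision matrix over fruit-trait groups, and a
    nine-scenario demographic simulator (faunal distance-weighted
    migration, post-megafauna isolation, and six human-dispersal
    scenarios) that generates nuclear SNP and chloroplast haplotype
    datasets for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    geosphere,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    knitr,
    rmarkdown,
    ggplot2
Config/testthat/edition: 3
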