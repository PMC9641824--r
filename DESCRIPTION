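Package: migrobiome
Title: Linking Raptor Migration Movement to Cloacal Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline connecting long-distance raptor migration to
    cloacal microbiota. Segments GPS tracks into migratory and stopover days
    with rhumb-line geodesy, detects arrival, death and connection-loss
    endpoints, and accounts migration distances; computes the scaled mass
    index of body condition; carries amplicon sequence variant tables through
    contaminant, taxonomy and read-depth filtering plus rarefaction; measures
    alpha diversity (Shannon, Chao1, Faith's phylogenetic diversity) and beta
    diversity (Jaccard, Bray-Curtis, unweighted and weighted UniFrac) with
    permutational multivariate analysis of variance, dispersion homogeneity
    tests and principal-coordinate ordination; runs bias-corrected
    differential-abundance tests; and fits the demographic and migration
    statistics (Welch tests, Scheirer-Ray-Hare, AICc model sets) that tie the
    two data streams together. A synthetic-data module generates tracks,
    morphometrics and Dirichlet-multinomial communities with planted effects
    so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    phyloseq,
    picante,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
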