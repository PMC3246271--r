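Package: synrate
Title: Spontaneous Mutation Rates from Synonymous Substitutions in
    Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers spontaneous base-substitution rates from synonymous
    mutations accumulated by clones sampled from experimental evolution
    lines. Counts per-type synonymous target sites on an annotated
    bacterial genome (both the one-third approximation and full
    per-mutation-type opportunity enumeration), fits a blocked Poisson
    maximum-likelihood model that corrects for the pseudo-replication of
    clones sharing ancestry within a population, attaches Tukey jackknife
    confidence limits by deleting whole populations, tests the
    composition-corrected mutational spectrum (transition:transversion
    ratio and GC->AT bias) with exact binomial tests, and screens clones
    with per-clone dN/dS. A forward simulator with star-like
    within-population genealogies generates annotated genomes and mutation
    tables under known per-type rates for end-to-end validation. Ships the
    mutation table of a 19-clone, eight-population long-term E. coli
    resequencing study as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
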