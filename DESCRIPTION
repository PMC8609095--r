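Package: mimicscreen
Title: Molecular Mimicry Screening of Thyroid Autoantigens Against
    CNS-Expressed Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening pipeline for molecular mimicry between the three
    classical thyroid autoantigens (the thyrotropin receptor, thyroglobulin
    and thyroperoxidase) and proteins expressed in the central nervous
    system, motivated by steroid-responsive encephalopathy associated with
    autoimmune thyroiditis (SREAT). Provides a protein catalog with
    keyword and deny-list filtering, an in-house Smith-Waterman local
    aligner with affine gaps and Karlin-Altschul E-value statistics, an
    interval-coincidence analysis that classifies overlaps between
    homology segments, published epitopes and reference segments
    homologous to the SREAT autoantigens (alpha-enolase, AKRIAI, DDAHI),
    structural-domain mapping, tissue-expression cross-referencing, a
    synthetic catalog generator with planted homologies for end-to-end
    validation, and publication-style homology track plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
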