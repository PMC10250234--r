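Package: rrnflank
Title: Covariation Analysis of Pre-16S rRNA Leader and Trailer Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts the leader and trailer regions flanking annotated 16S
    rRNA genes from bacterial genome assemblies using anchored fuzzy motif
    search (trailer anchor and boxC), clusters the flank pairs with a
    structure-aware distance built on equilibrium basepair probabilities,
    infers per-clade consensus secondary structures by progressive alignment
    and covariance-bonus folding, and scores each consensus basepair by the
    number of distinct canonical pair types and mismatches observed
    (colour and tint classes). Quantitative features of the leader-trailer
    helix (hLT duplex length and threshold class, boxA detection and
    boxA-boxC spacing) are profiled per pair. A synthetic-genome generator
    plants flank architectures with compensatory substitutions along a
    clade-structured phylogeny, providing ground truth for end-to-end
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    stringr,
    rlang,
    ggplot2,
    generics,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
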