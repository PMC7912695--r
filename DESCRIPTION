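Package: desertam
Title: Amplicon Profiling and Community Null Models for Arbuscular
    Mycorrhizal Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for closed-reference profiling of arbuscular
    mycorrhizal (AM) fungal communities from paired-end SSU rRNA amplicon
    reads: primer matching and trimming, quality filtering, read-pair merging,
    best-hit assignment of merged reads to virtual taxa (VT) with identity and
    coverage thresholds, Hill-number diversity with asymptotic extrapolation,
    neighbor-joining phylogenies with mean-pairwise-distance community
    structure statistics, ordination of community dissimilarities with
    environmental vector fitting, and multi-scale randomization tests of
    desert-habitat affiliation. Includes a fully seeded synthetic-data
    generator (reference catalogue, phylogeny, communities, raw reads) with
    known ground truth for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
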