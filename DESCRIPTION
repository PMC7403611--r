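Package: domainsep
Title: Interdomain Split Counts and Distance-Ratio Statistics for
    Gene-Family Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how cleanly a gene-family phylogeny separates two
    domains of life (archaea and bacteria). Counts the minimal number of
    interdomain branches (splits, s) with an exact two-state parsimony
    dynamic program, locates the split nodes and aggregates their support
    values, and computes the intra- versus inter-domain patristic distance
    ratios D-bar and D from branch lengths. Includes a leaf-label
    permutation null model at fixed domain proportions, a synthetic tree
    generator with planted domain structure and known ground truth, and
    batch reporting over tree collections in newick format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
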