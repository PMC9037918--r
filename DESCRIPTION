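Package: radwolb
Title: Depth-Based Sexing, Wolbachia Strain Typing and COI Haplotype
    Analysis for Aedes Mosquitoes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a ddRAD-seq analysis chain for
    Aedes albopictus field samples: read-depth based sex classification
    (per-feature linear models with batch adjustment, PCA label screening
    and a maximum-margin classifier), diagnostic-SNP based typing of the
    wAlbA/wAlbB Wolbachia endosymbiont strains via a Laplace-smoothed
    allele-fraction score and log-score logistic regression, qPCR
    crossing-point processing into infection calls and relative densities
    with the accompanying incidence and density statistics, and COI
    haplotype collapsing with Kimura 2-parameter distances,
    neighbour-joining trees, bootstrap support and minimum spanning
    networks. Ships seeded synthetic-data generators emulating each input
    so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    car,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
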