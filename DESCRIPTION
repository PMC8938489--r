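Package: preyspectra
Title: Prey Spectra of Carnivorous Plants from DNA Metabarcoding and
    Macro Photography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for qualitative and quantitative prey
    spectra analysis of carnivorous plants that combines bulk-sample DNA
    metabarcoding with in-situ macro photography. Implements dual-database
    (BOLD/GenBank-style) consensus taxonomy per OTU, relative-abundance
    cleaning of OTU tables, family-level pooling with an exclusion cascade
    for contaminants and plant parasites, a conservative pictorial
    plausibility control reconciling barcoding detections with photo
    annotations, presence/absence community statistics (binary Bray-Curtis
    dissimilarity, ANOSIM with permutation tests, SIMPER decomposition),
    photo-derived prey quantification per cm of trapping-leaf length with
    Kruskal-Wallis and Dunn-Bonferroni comparisons, and a seeded synthetic
    data generator emulating the complete input family for reproducible
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
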