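Package: metaboweb
Title: Linking Isolate Exometabolite Profiles to In Situ Microbe-Metabolite
    Dynamics in Biological Soil Crust
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether uptake/release behaviour measured in
    isolate spent-media exometabolomics predicts microbe-metabolite
    correlations in intact soil communities. Implements peak-area table QC
    and filtering (two-fold dynamic range, killed-control ANOVA), fold-change
    classification of isolate exometabolite profiles, single-copy
    ribosomal-protein marker matching of isolates to environmental taxa,
    Spearman correlation networks with FDR control, an exact two-tailed
    binomial test of sign concordance, foodweb edge construction, pathway
    level expression summaries, and a seeded synthetic wet-up data generator
    with known ground truth for end-to-end validation.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
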