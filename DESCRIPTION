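Package: pfasdef
Title: Rule-Based Classification of Per- and Polyfluoroalkyl Substances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes the major structural definitions of per- and
    polyfluoroalkyl substances (PFAS) -- OECD 2021 and 2018, the TSCA 2021
    working definition, the EPA PFAS structures list versions, the Drinking
    Water Contaminant Candidate List 5 definition, and a combined
    substructure-plus-fluorine-fraction definition -- as data-driven rule
    sets over molecular graphs. Parses SMILES and SDF (V2000) structures,
    profiles every carbon (fluorination, saturation, attached halogens and
    hydrogens), computes molecular-formula fluorine descriptors (atom-count
    fraction with or without hydrogen, mass fraction, fluorine-to-carbon
    ratio), classifies structures under any registered definition with
    per-clause evidence, and compares definitions over a compound library
    (overlap, set differences, gap candidates). Includes a fixture corpus of
    literature compounds and a seeded synthetic fluorochemical generator for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
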