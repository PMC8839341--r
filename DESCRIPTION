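Package: polyestermz
Title: Combinatorial Identification of Polyester Oligomer Migrants by Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico identification of polyester oligomers
    migrating from food-contact can coatings. Enumerates linear and cyclic
    ester oligomers from a monomer library with water-loss accounting,
    computes singly charged adduct m/z values (H+, NH4+, Na+, K+, -H),
    annotates centroided MALDI-TOF and LC-MSn peak lists, detects
    homologous repeat-unit series and monomer-exchange mass deltas to infer
    the starting monomers, enumerates ester-cleavage product ions, and
    applies a Cramer-class / threshold-of-toxicological-concern screening
    rule. Includes a seeded synthetic-spectrum generator so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
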