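Package: compositemap
Title: Composite Genetic Linkage Maps by Anchor-Based Marker Merging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Merges two or more independently constructed genetic linkage
    maps into a single high-density composite (reference) map. Homologous
    linkage groups are identified from shared anchor markers, candidate
    component groups are ranked by a fit value (order correlation times the
    log of the shared-marker count), and markers unique to a component group
    are projected onto the growing composite group by least-squares
    regression of anchor positions. Includes marker-name harmonisation,
    colinearity pre-screening, distal-end trimming, a quality-control
    surface (composite-component order correlations, per-linkage-group
    summaries, a chi-square test of multicopy marker distribution, redundant
    marker flagging) and a seeded synthetic-map generator for end-to-end
    validation against a known truth.
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
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
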