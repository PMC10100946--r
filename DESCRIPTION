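Package: oralgut
Title: Oral-to-Gut Microbial Invasion Analysis for In Vitro Colon Metagenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies metagenomic species pangenomes (MSPs) from gene-level
    abundance tables mapped against paired gut and oral gene catalogues,
    assigns each species an ecological niche (gut, oral, or not determined)
    from baseline stool and raw-saliva samples, and tracks oral invader
    species across the luminal and mucosal compartments of a two-compartment
    continuous colon fermenter over an 11-day time course. A synthetic-data
    module simulates the fermenter (logistic chemostat lumen, mucin-bead
    mucosal compartment, saliva enrichment and spike-in schedule) together
    with multinomial read-to-gene sequencing, so the whole pipeline runs and
    is testable with no external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    vegan,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
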