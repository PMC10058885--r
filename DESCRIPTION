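Package: credra
Title: Genotoxicity and DNA Methylation Typing from RAPD and CRED-RA Band
    Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring heavy-metal genotoxicity and cytosine
    methylation in plants from dominant-marker band profiles. Implements
    genomic template stability (GTS) and polymorphism statistics over RAPD
    presence/absence matrices, four-type methylation classification of
    CRED-RA lane triplets (undigested / HpaII / MspI) with total, full and
    semi methylation pattern ratios, a ground-truthed synthetic-data
    generator (in-silico CCGG amplicons, dose-conditioned methylation
    states, enzyme digestion and priming-site mutation), and an end-to-end
    reporting pipeline with tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
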