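Package: ericakey
Title: Multi-Access Identification Keys with Probability Ranking and
    Quarter-Degree-Square Mapping
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, scriptable engine for multi-access species
    identification keys built on coded character-state matrices, modelled on
    the identification aid for the heath genus Erica. Taxa are coded with
    possibly polymorphic states across character groups (morphology,
    phenology, geography); users identify specimens by strict matching or by
    a probability ranking in which each character group contributes the
    reciprocal of the number of taxa carrying the selected state, so rare
    states weigh more than common ones. Includes taxon comparison tables,
    checklist handling (accepted names, synonyms, unplaced names),
    quarter-degree-square (QDS) geocoding and per-square taxon lists, KML
    export of grid squares and occurrence points for Google Earth, coverage
    reports contrasting gridded and point distributions, deterministic
    synthetic-data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
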