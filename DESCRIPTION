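Package: volcontrib
Title: Volunteer Contribution Analytics for Citizen-Science Biological Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing patterns of volunteer contribution in
    opportunistic biodiversity recording schemes. Ingests Darwin-Core-like
    occurrence tables, parses Ordnance Survey (OSGB) grid references at mixed
    precision, computes per-volunteer engagement metrics (activity ratio,
    relative activity duration, variation in periodicity, observation count),
    clusters volunteers into engagement profiles validated by average
    silhouette width, aggregates recording effort to 1-km grid cells with
    hotspot rankings and rank correlations, summarises taxonomic composition
    and checklist coverage, and screens species traits against record counts
    with overdispersion-robust quasipoisson regressions. A synthetic
    occurrence-record generator with planted engagement archetypes, effort
    hotspots and trait-linked recording rates makes the full pipeline testable
    without access to any proprietary dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
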