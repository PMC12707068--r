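Package: spatcons
Title: Spatial Conservation-Accounting on Abstract Equal-Area Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for area-based conservation accounting on gridded
    landscapes: coverage uplift when biosphere reserves are counted
    alongside protected areas and OECMs, representativeness of binary
    opportunity templates against a random-placement baseline, a
    rarity-weighted Conservation Value Index with min-max
    standardization, bivariate sextile-matrix expansion prioritization,
    and designation-aligned piecewise habitat-quality trend regression.
    Includes a seeded synthetic-world generator (land mask, province
    partitions, autocorrelated binary templates, three reserve networks
    with controlled overlap, annual quality stacks with known trends,
    and a smooth pressure surface) with full ground-truth bookkeeping,
    so every stage is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
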