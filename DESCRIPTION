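Package: annolite
Title: Annotation-Driven Compact Candidate Databases for Non-Target
    Small-Molecule Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds compact, exposomics-oriented candidate databases from
    large compound knowledge-base dumps by selecting annotation-category
    fingerprints, mapping entries to parent compounds, collapsing
    stereoisomers by InChIKey first block, and filtering element, mixture
    and charge artefacts. Provides exact-mass (ppm window) and formula
    candidate retrieval with metadata-weighted, max-normalized scoring and
    ranking; bucketed rank benchmarking; gap analysis against suspect
    lists; transformation-product predecessor/successor statements; and a
    deterministic synthetic fixture generator with an independent
    reference implementation of the construction rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
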