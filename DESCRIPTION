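Package: pigeonpix
Title: Analysis of Pigeon Discrimination of Pixelated LED Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative forced-choice discrimination of
    binary 5x7 pixel patterns by pigeons. Represents and classifies pixel
    patterns against a training pair, computes discriminability indices and
    their variants, performs translation-tolerant pattern registration, builds
    pixel-wise salience (classification-image) correlation maps with cluster
    extraction, and runs replication, relativity, team-concordance and
    inter-individual analyses. Includes a seeded generative choice simulator
    (logistic choice on per-pixel evidence weights) so that every stage of the
    pipeline can be exercised and validated on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
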