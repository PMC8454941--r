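Package: ednaIBCH
Title: Biotic Index Assessment of Rivers from eDNA Metabarcoding and Kick-Net Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing macroinvertebrate-based ecological assessment of
    rivers from environmental DNA (eDNA) metabarcoding against traditional
    kick-net monitoring. Cleans replicated OTU read-count tables with
    control-based read thresholds and k-of-n replicate-consistency filters,
    computes the Swiss IBCH macroinvertebrate biotic index (0-20 score, five
    ecological-state categories) from kick-net community counts, predicts the
    index from OTU presence/absence with a taxonomy-free random-forest
    procedure, and quantifies method agreement via adjusted R-squared, Cohen's
    kappa, and category deviations. A synthetic-data module generates paired
    eDNA/kick-net datasets from a latent site-quality model with known ground
    truth, so every stage is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
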