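Package: amylokin
Title: Aggregation Kinetics and Fibril Morphometry for Amyloid Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Chemical-kinetics analysis of amyloid-beta (Abeta42) aggregation
    dominated by monomer-dependent secondary nucleation. Implements the
    integrated rate law for fibril mass growth together with its exact
    moment-equation counterpart, global perturbation fitting of multi-condition
    thioflavin-T traces with basin-hopping, mechanistic hypothesis ranking by
    information criteria, half-time dose-response summaries, the sqrt(k+/k2)
    fibril-length scaling prediction, and AFM/TEM fibril morphometry statistics
    using a sensitivity-aware total-error convention. A deterministic synthetic
    data generator with planted ground truth stands in for plate-reader and
    microscopy inputs so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
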