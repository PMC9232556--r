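Package: hscurves
Title: Habitat Suitability Curves for Macroinvertebrate Communities and
    Functional Feeding Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds habitat suitability criteria for benthic
    macroinvertebrates from microhabitat survey data. Implements habitat
    availability, utilization and preference curves (HAC/HUC/HPC) over
    water flow velocity, depth and substrate category, suitability-index
    normalization, per-campaign standardization with explicit
    campaign-combination strategies, the composite K suitability
    coefficient (family richness, Shannon diversity, EPT abundance and
    density), functional feeding group classification from 10-point
    trait allocations, an ANOSIM pre-check for pooling field campaigns,
    and a synthetic microhabitat data generator with known ground truth
    for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
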