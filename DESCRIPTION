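Package: threeseb
Title: Three-Source Energy Balance Modelling of Vineyard Evapotranspiration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions vineyard evapotranspiration into vine transpiration,
    cover-crop transpiration and soil evaporation using a three-source
    surface energy balance (3SEB) model driven by radiometric surface
    temperature and standard tower meteorology, with a two-source (TSEB)
    baseline. Includes Priestley-Taylor canopy initialization with
    iterative alpha reduction, a Monin-Obukhov resistance network, a
    two-layer Campbell-Norman radiative transfer scheme, decomposition of
    ecosystem leaf area index into vine and cover-crop components with
    phenology-driven transitions, eddy-covariance energy-closure
    corrections, evaluation statistics, and a synthetic flux-tower data
    generator so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
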