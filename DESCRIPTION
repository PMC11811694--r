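Package: agihabitat
Title: Aerobic Growth Index Habitat Viability and Predator-Prey Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies climate-driven change in the viable habitat of
    Southern Ocean species and in their three-dimensional habitat overlap
    using the extended aerobic growth index (AGI), an oxygen supply-demand
    metabolic index.  Provides grid and volume bookkeeping on regular
    lon-lat-depth ocean grids, seawater conversions (in situ temperature,
    density, oxygen solubility and partial pressure), construction of 3-D
    species habitat masks from occurrence-probability maps, volume-weighted
    percentile thresholds, viable-habitat volumes and overlaps, scenario
    drift correction and temperature/oxygen attribution, and a fully
    synthetic seeded ocean generator so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
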