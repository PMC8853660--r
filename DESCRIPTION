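Package: esconnect
Title: Functional Connectivity of Ecosystem Service Supply Across Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps functional connectivity between supply areas of multiple
    ecosystem services (ES) across a heterogeneous landscape. Delineates
    top-value supply areas from gridded ES value surfaces for plant
    agriculture (PA), waterflow regulation (WF) and landscape aesthetics
    (LA); computes five directed overlapping link types by zonal-sum
    weighting where supplies co-occur, and three topographic link types by
    least-cost-path corridors traced downslope over a DEM from WF supply
    areas to sub-basin outlets, extended through downstream influential
    landscape features (wetlands, floodplains, riparian areas); normalizes
    and amalgamates link weights into a single connectivity surface; and
    reports land-use/land-cover coverage of supply areas and corridors.
    Includes a deterministic synthetic-landscape generator (terrain,
    sub-basins, land cover, ES supply rasters) and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
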