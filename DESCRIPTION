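Package: poreskel
Title: Curve-Skeleton Pore-Network Modelling and Microbial Carbon Turnover in Soil Micro-CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric modelling of the 3D pore space of soil (and other porous
    media) imaged by X-ray micro-computed tomography. Extracts a one-voxel-thick
    curve skeleton by topology-preserving homotopic thinning, segments it into
    maximal simple branches, partitions the pore space into connected regions by
    nearest-branch assignment, and builds an attributed relational graph whose
    nodes carry pore volumes and inertia centres and whose arcs carry exact
    contact-surface areas. The graph supports a fast simulation of microbial
    mineralization of organic matter (microbial biomass, dissolved, soil and
    fresh organic matter, and CO2 pools) with diffusion of dissolved organic
    matter solved by implicit or explicit Euler schemes, a non-spatialized 0D
    baseline, and calibration of the diffusive overall conductance against a
    voxel-level finite-difference diffusion reference. Seeded synthetic volume
    generators (tubes, tori, junctions, cavity cubes, correlated random porous
    media) make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
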