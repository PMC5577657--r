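Package: seedcontact
Title: Seed-Soil Contact Quantification from X-Ray Computed Tomography Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the in-situ contact between a seed and the surrounding
    soil from 3-D X-ray computed tomography volumes. Segments air, soil and
    seed phases, closes the internal air space of a germinating seed to obtain
    a closed surface, dilates the soil by one voxel and classifies seed surface
    faces as contact or non-contact, reporting the seed-soil contact percentage
    and contact area. Builds ring-shaped shells (100 and 300 micrometre at
    20 micrometre voxels) around the seed and computes "iceberg effect"
    metrics: the soil volume effect, the surface effect and the change in soil
    mass with distance. Includes a synthetic phantom generator (spherical and
    star-shaped seeds in granular soil) with analytic ground truth for
    validation, replicate summarisation and a polyline length tool, plus
    readers and writers for TIFF stacks and NRRD volumes with voxel-size
    metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
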