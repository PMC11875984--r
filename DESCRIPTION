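Package: cellContacts
Title: Cell-Cell Interaction and Polarization Profiling in 3D Multiplexed Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies candidate cell-cell interactions and cell-centric
    marker polarization in multi-channel 3D immunofluorescence volumes
    (e.g. cyclic immunofluorescence). Builds a cell neighborhood graph
    from labeled cell centers by filtering a 3D Delaunay triangulation to
    its Gabriel graph, integrates voxel intensities inside cylinders or
    bicones around each edge into per-channel one-dimensional interaction
    profiles, ranks edges by a mean Minkowski profile distance after
    length normalization by linear interpolation, and summarizes marker
    polarization around single cells as 12-sector clock-face profiles
    relative to a viewing plane. Includes a synthetic-volume generator
    with planted ground truth for end-to-end validation and a scriptable
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
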