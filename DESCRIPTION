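Package: sinusnav
Title: Monocular Vision-Based Sinus Surgery Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for monocular endoscope navigation against a preoperative
    CT surface model. Implements an incremental sliding-window SLAM core
    (two-view bootstrap, triangulation, local bundle adjustment),
    semi-automated first-frame registration to a rendered CT reference view
    via robust PnP, continuous monocular-scale recovery by ray-casting
    reconstructed points onto the CT mesh, mapping of SLAM poses into CT
    coordinates, guidance projections (viewing-axis tissue intersection,
    triplane voxel indices), trajectory evaluation metrics (translation and
    rotation errors, similarity alignment, half-split target registration
    error, fiducial point-to-mesh distance), and a synthetic scene generator
    for end-to-end testing of the pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
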