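Package: markermorph
Title: Fiducial Marker Morphometry from Longitudinal CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Localizes implanted radiopaque fiducial markers in CT volumes,
    builds scapular and humeral anatomical coordinate frames from bony
    landmarks, registers longitudinal scans by rigid least-squares (Kabsch)
    fitting, imputes virtual bone markers from their rigid-body relationship
    to physical bone markers, and computes inter-marker lengths, swap-averaged
    quadrilateral areas, projected humeral orientation angles, repeat-scan
    precision, and longitudinal change statistics.  Includes a synthetic CT
    phantom generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
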