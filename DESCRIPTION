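Package: facetouch
Title: Geometric Detection and Evaluation of Hand-Face Contact Gestures
    from 3D Skeleton Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-independent pipeline for monitoring hand-face contact
    behavior from time-stamped 3D body-joint streams (32-joint Azure-Kinect-style
    skeletons). Models the head as a sphere centered between the ear joints,
    detects contact frames when a thumb joint enters a contact volume scaled to
    70% of the inter-ear distance, classifies the touched face area by
    nearest-landmark (Voronoi-style) assignment with a 75% low-risk threshold,
    groups labeled frames into contact events, checks interpersonal distance
    between tracked bodies, and writes behavioral reports. Includes the full
    event-level evaluation protocol (temporal event matching, confusion matrices
    with occlusion and missed-event semantics, per-class accuracy, precision and
    sensitivity, overall accuracy, Cohen's Kappa, and risk/no-risk class
    clustering) and a synthetic skeleton-gesture simulator with anthropometric
    head-breadth presets, joint jitter and dropout, so the whole system is
    testable without a depth camera.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
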