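Package: larvatrack
Title: Multi-Animal Tracking and Locomotion Analysis for Dark-Field
    Recordings of Small Animals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tracks multiple bright animals (Drosophila larvae, C. elegans
    worms) on a dark background in grayscale image sequences.  Segments
    animals by minimum-intensity background subtraction, extracts a
    contour-based posture model (head, midline spine points with local
    radii, tail, center of mass), links detections across frames by
    bipartite assignment (Hungarian or greedy, with center-of-mass,
    mid-spine or contour-overlap costs), corrects head/tail orientation
    over whole trajectories, and derives posture, motion and
    stimulus-related features.  Includes a synthetic scene generator with
    exact per-frame ground truth and a deviation evaluator for accuracy
    quantification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    pracma,
    png,
    tiff,
    yaml,
    stats,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
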