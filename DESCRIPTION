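Package: stereoannot
Title: Authoring, Tracking and Stereoscopic Rendering of Annotated
    Side-by-Side Surgical Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mixed-reality enhancement of side-by-side (SBS)
    stereoscopic robotic-assisted surgery video. Tracks teacher-annotated
    elements through the left-eye view with a discriminative normalized
    cross-correlation template tracker, estimates the horizontal disparity
    of each annotation by band-restricted block matching with subpixel
    refinement so virtual overlays appear at the correct depth, manages
    intervention metadata, named sections and annotation keyframes in a
    canonical JSON document model, renders annotation overlays into SBS or
    red-cyan anaglyph output (including sections-only compaction and speed
    decimation), generates synthetic stereo scenes with ground truth for
    hermetic benchmarking, implements the teacher-authoritative
    synchronized playback protocol, and provides the summary statistics
    and one-sample tests used to evaluate stereoscopic training tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
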