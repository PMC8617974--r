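Package: fencetrack
Title: Riding-Line Extraction from Pose Detections in a Video Fence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to turn per-frame human pose detections (COCO-17 keypoints)
    from a fixed camera into riding lines through a rectangular region of
    interest (the "fence"). Provides a spatiotemporally aware nearest-centre
    tracker with a diagonal-scaled matching gate, a three-step track-fragment
    merger that repairs identity fragmentation, fence membership and valid-path
    extraction with dwell-time estimates and ride-mode/team metadata summaries,
    homography mapping of image paths to real-world plane coordinates, and a
    deterministic scene simulator that generates detection streams with ground
    truth for end-to-end validation. Includes a batch command-line pipeline
    that reads detection and annotation JSON plus a scene configuration and
    writes a per-fence report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
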