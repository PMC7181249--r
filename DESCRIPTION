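Package: herdcount
Title: Counting Cattle in Overlapping UAV Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts light-coated cattle in sequences of
    overlapping aerial survey images. Implements a four-stage pipeline:
    grid-based region-of-interest selection with a pluggable tile
    classifier, quadrant-wise color-space mask generation (CMY channels
    plus a contrast-enhancing pseudo-CIELAB channel, brightness-corrected
    thresholds and histogram-valley selection for the yellow channel),
    mask fusion and morphological cluster splitting with rule-based count
    estimation, and sequential overlap de-duplication across frames.
    Includes a seeded synthetic-scene and survey generator with full
    ground truth, image registration for translation recovery, and
    count-based evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
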