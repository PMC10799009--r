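Package: wbgait
Title: Walking-Bout Assembly and Agreement Validation for Wearable Gait Speed
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing and validation toolkit for real-world walking
    speed estimated from wearable sensors. Converts per-second cadence and
    stride-length traces plus detected initial-contact events into
    definition-compliant walking bouts (stride interpolation, stride
    selection, bout assembly, per-bout digital mobility outcome
    aggregation, turn-based complexity classification), matches bouts
    between a device and a reference system by temporal overlap, and
    computes two-tier agreement statistics: true-positive (per-bout) and
    combined (per-task or per-recording median) evaluations with mean and
    relative errors, Bland-Altman limits of agreement, ICC(2,1) with
    F-based confidence intervals, sample-wise detection metrics, and
    confounder-stratified summaries by bout duration, walking speed and
    gait complexity. Includes a seeded generator of paired
    reference/device gait-event streams for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
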