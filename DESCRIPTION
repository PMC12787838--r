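Package: imugait
Title: IMU-Based Gait Analysis for the Six-Minute Walk Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for six-minute walk tests recorded with three
    body-worn inertial measurement units (both shanks and the sacrum): reading
    and validating raw 9-DOF sensor streams, quaternion strap-down orientation
    estimation with complementary accelerometer/magnetometer drift correction,
    activity classification, gait-cycle detection and pairing, time-normalized
    (0-100%) average motion profiles, walk metrics (steps, distance, step
    length, speed) and per-minute straight-segment angle snapshots, plus
    test-retest reliability statistics (Cronbach's alpha and the one-way
    single-measure intraclass correlation coefficient) with qualitative
    banding. Includes a forward simulator of 6MWT sessions with full ground
    truth so every stage is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
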