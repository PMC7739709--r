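Package: sitski
Title: Speed, Power and Poling Kinematics in Cross-Country Sit-Skiing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrative framework for analysing cross-country
    sit-skiing sessions recorded with a GNSS sports watch, a wrist-worn
    inertial measurement unit and a heart-rate monitor.  The package maps
    1 Hz GNSS tracks onto a sectioned reference course, derives virtual
    split times and section speeds, decomposes external power into
    gravity, ski-snow friction and aerodynamic drag terms, estimates the
    ski-snow friction coefficient from passive glide tests, detects pole
    plants from gyroscope and accelerometer signals to compute poling
    cycle rate and length, and summarises training intensity per terrain
    relative to peak heart rate, maximal speed and maximal power.  A
    seeded simulator generates complete synthetic sessions (GNSS + IMU +
    heart rate with ground truth) so the whole pipeline is testable
    without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
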