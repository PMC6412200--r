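Package: imuhar
Title: Activity Recognition for Older People from Wearable IMU Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-based recognition of activities of daily living
    (sit/stand, laying, walking, stairs, transitions) from 25 Hz wearable
    inertial measurement unit recordings of older people, hardened against
    device inconsistencies. Implements gravity/body acceleration separation,
    a pinned 254-feature axis-dependent and 90-feature rotation-invariant
    feature manifest, cross-device baseline harmonization, a two-rule
    orientation router built on a three-dimensional binned Kolmogorov-Smirnov
    distance, Relief-F feature ranking, class-weighted RBF support vector
    machines with stratified grid search, temporal majority-vote label
    smoothing, three convolutional network input layouts trained natively in
    R, and a fully seeded synthetic IMU cohort generator for end-to-end
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
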