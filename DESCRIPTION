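Package: eegfluidity
Title: Extreme-Value Dynamics Fluidity, Microstates and Kinematics for
    High-Density EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for large-scale brain dynamics in freely
    behaving rodents recorded with high-density surface EEG grids.
    Implements time-resolved dynamics fluidity (the extremal index of
    log-distance exceedances around reference topographies, estimated
    with the Suveges closed-form maximum-likelihood estimator), EEG
    microstate segmentation by correlation-distance k-means and by
    global-field-power peak clustering, transition-based microstate
    fluidity, minimum-description-length sequence complexity, multitaper
    relative band power, pose-track normalization with derived speed and
    egocentric head movement, and the bootstrap Kolmogorov-Smirnov and
    mutual-information statistics used to compare genotypes and
    conditions. A synthetic-data module generates multichannel series
    with controllable microstate switching and temporal persistence, and
    open-field pose tracks under arbitrary camera placement, so the full
    pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    Matrix,
    jsonlite,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
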