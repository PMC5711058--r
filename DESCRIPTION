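Package: transitdose
Title: Entrance and Exit Dose Verification for Megavoltage Photon Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-vivo dosimetry reference-dose computation for 6 MV
    photon beams: reconstruction of central-axis doses from percentage
    depth-dose and output-factor beam data, derivation and application of
    backscatter correction factors (BCF) for entrance and exit dose points,
    synthesis of 2D absolute dose planes from orthogonal 1D water-tank scan
    profiles, and 2D absolute gamma analysis (dose difference /
    distance-to-agreement) over full-field and central-80% regions of
    interest. Includes an analytic synthetic beam-data generator and
    treatment-planning-system (TPS) failure-mode emulators so the whole
    pipeline can be exercised end to end without measured data, and bundled
    measured BCF tables for two clinical 6 MV beams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
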