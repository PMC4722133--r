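Package: svhdecay
Title: Exponential and Power-Law Models of Short-Term Vestibular Forgetting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the time course of the decaying
    sensation of roll tilt recorded as the subjective visual horizontal (SVH)
    during gondola centrifugation.  Fits three-parameter exponential
    (A*exp(-b*t) + C) and power (A*t^-b + C) forgetting curves to per-run
    setting series by unweighted least squares with a multistart
    variable-projection search, averages runs into individual summaries,
    compares the two model families by RMS error at run, individual and group
    level, pools cohorts by time-binning or by concatenating all settings, and
    generates study-conformant synthetic cohorts to demonstrate how averaging
    heterogeneous exponential decays erodes the exponential model's advantage.
    Also includes swing-out gondola centrifuge stimulus kinematics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), minpack.lm, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
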