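Package: iconqa
Title: Workflow Uncertainty Analysis for Frameless Stereotactic Radiosurgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the total geometric uncertainty of the
    frameless Gamma Knife Icon treatment workflow. Parses intrafraction
    motion-monitoring (HDMM) log files, computes gating-threshold truncated
    time-weighted (AUC) mean displacements and post-CBCT residual setup
    statistics, evaluates image-guidance registrations via target
    registration error (TG-132 point method) and known-offset recovery,
    and assembles systematic and random uncertainty components into a
    quadrature budget with sub-threshold probability estimates and
    literature setup-margin recipes (van Herk, Stroom). Includes a
    synthetic motion and fixture generator so the full pipeline is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
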