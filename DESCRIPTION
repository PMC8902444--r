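Package: acheiuse
Title: Drug Utilization Before and After Acetylcholinesterase Inhibitor
    Initiation in Prescription Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for new-user drug-utilization studies built on
    individual-level pharmacy dispensing registries. Constructs refill-based
    acetylcholinesterase inhibitor (AChEI) use periods, classifies medication
    persistence from refill patterns, applies an incident-user
    inclusion/exclusion cascade, computes windowed prevalence of co-medication
    groups (with Wilson score intervals and small-cell suppression) from four
    years before to two years after treatment initiation, and compares the
    study population with the general population via year-shifted direct age
    standardization and prevalence ratios. Includes a synthetic registry
    generator with configurable statistical structure so the full pipeline is
    testable without access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
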