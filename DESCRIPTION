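Package: betapet
Title: Behavioral Task-Associated Differential FDG-PET Analysis
Version: 0.1.0
Authors@R:
    person("Beta-PET", "Maintainers", email = "maintainers@betapet.dev",
           role = c("aut", "cre"))
Description: Tools for behavioral task-associated PET ("beta-PET"): per-region
    delta-SUV quantification between two task-phase FDG scans, freezing-behavior
    scoring from frame-wise activity traces, linear mixed-model and correlation
    statistics, leave-one-out cross-validated classification, and ordinal-trends
    canonical-variates network analysis. Includes a synthetic phantom-cohort
    generator so the full pipeline is testable without scanner data, a minimal
    NIfTI-1 reader/writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
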