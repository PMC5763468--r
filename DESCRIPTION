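Package: ternet
Title: Ternary-State Integer Linear Programming for Signaling Network
    Inference and Compound-Effect Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers cell-specific signaling subnetworks from compound
    perturbation phosphoproteomic profiles by mixed-integer linear
    programming over a literature-curated signed network, and
    re-optimizes the inferred subnetwork per compound to predict
    treatment effects.  Protein states are discretized to ternary
    values (down-regulated, no-change, up-regulated) from log2
    treatment/control ratios; the optimization trades off data fit
    against network simplicity under prior-knowledge constraints and
    reports pathway alterations, cell-function outcome vectors, and
    similarity scores between compounds.  Includes a brute-force
    enumeration oracle, leave-one-out cross-validation, a synthetic
    ground-truth generator, and a command-line interface.  The
    mixed-integer programs are solved with the HiGHS solver through
    the Python scipy bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH
    for the MILP solver backend
Config/testthat/edition: 3
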