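Package: phasefit
Title: Interference-Phase Models for Disjunction-Effect Decision Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for wave-interference models of binary decisions under
    uncertainty. Extracts interference-phase differences from known-condition
    decision probabilities and from event-related-potential (ERP) amplitude
    triplets, combines the known-condition phases into a predicted phase for
    the unknown condition using fixed paradigm-specific rules, and predicts
    the unknown-condition choice probability. Bundles published
    categorization-decision, two-stage gambling, prisoner's dilemma and ERP
    tables as fixtures with cell-by-cell reproduction reports, stability
    statistics (CV, RMSD, MAPE, uniform-window clustering probability), a
    synthetic-scenario generator with binomial response noise for parameter
    recovery studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
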