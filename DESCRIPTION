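Package: flexrand
Title: Flexible-Entry Multi-Arm Trial Design with Preference-Constrained
    Randomisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for designing and simulating flexible-entry multi-arm
    randomised trials in which each participant chooses an admissible subset
    of arms (a randomisation scheme) subject to a treatment-class constraint.
    Provides the scheme algebra, covariate-adaptive (Pocock-Simon marginal
    totals) minimisation with an independent state per scheme, a screening
    and accrual simulator with preference-driven scheme selection, the
    internal-pilot feasibility decision rule with design adaptation, and
    two-sample sample-size and power machinery (noncentral-t) with
    Bonferroni adjustment and attrition inflation. Ships a reference
    configuration for a four-arm contraceptive trial after endometriosis
    surgery (two long-acting arms versus pill or no treatment).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
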