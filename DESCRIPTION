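Package: survpath
Title: Survival Path Mapping for Dynamic Prognosis on Time-Series Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds tree-structured survival path models from longitudinal
    clinical records. Raw per-visit time-series data are binned into fixed
    width time slices on each patient's own timeline, continuous markers are
    dichotomized at the cutoff recommended by a time-dependent ROC curve, and
    a recursive per-node feature-selection cascade (Kaplan-Meier univariate
    screen, collinearity pruning by AIC, backward elimination on the Cox
    partial likelihood, likelihood-ratio variable importance) chooses one
    binary split variable per node and time slice. The resulting path tree is
    annotated with node-level median residual survival and fixed-horizon
    survival rates, and supports downstream node-versus-node survival
    comparison, treatment-arm analysis, treatment-to-transition tables, and
    per-slice discrimination via Harrell's concordance index. A synthetic
    longitudinal cohort generator with planted proportional-hazards structure
    is included for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    ape,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
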