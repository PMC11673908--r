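Package: cyclogait
Title: Dynamic Centre-of-Pressure Cyclogram Diagnostics for Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building centre-of-pressure (COP) cyclograms (butterfly
    diagrams) from dual-insole plantar-pressure recordings and for screening
    gait for balance impairment such as diabetic peripheral neuropathy.
    Detects gait events from vertical force traces, combines per-foot COP
    paths into a force-weighted cyclogram, extracts the ten cyclogram marker
    points per stride (rearmost/frontmost COP, single-support endpoints, and
    transfer-path intersections), and derives fifteen cyclogram parameters
    including a scatter-based Balance Index. Cohort-level classifier
    evaluation uses the Mann-Whitney U statistic, its rank-based effect size
    and AUC identities, ROC sweeps with the geometric-mean optimal threshold,
    and confusion percentages. A synthetic gait generator produces two-cohort
    insole recordings with planted marker geometry for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
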