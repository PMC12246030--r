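Package: rxpersist
Title: Treatment Persistence, Adherence and Competing-Risks Analysis of
    Prescription-Fill Registers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for drug-utilization studies on prescription-fill
    registers: new-user cohort assembly, construction of drug-coverage
    segments with a stockpiling rule, grace-period treatment episodes with
    discontinuation, reinitiation and within-class switching, treatment
    trajectories over a fixed horizon, adherence as proportion of days
    covered (PDC), the proportion of patients covered (PPC) over time,
    Aalen-Johansen cumulative incidence under competing risk of death, and
    Fine-Gray sub-distribution hazard regression fitted by IPCW-weighted
    partial likelihood. Includes a synthetic prescription-register
    generator with a ground-truth event log so every pipeline stage and
    estimator can be validated without access to register data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cmprsk,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
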