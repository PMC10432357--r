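Package: hipps
Title: Pregnancy Episode and Gestational Age Inference from OMOP-Style EHR Data
Version: 0.1.0
Authors@R:
    person("HIPPS", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers pregnancy episodes, pregnancy outcomes, and precisely
    dated pregnancy starts (last menstrual period) from longitudinal
    OMOP-CDM-style event tables. Implements the HIPPS approach: a
    hierarchy-based inference of pregnancy (HIP) built from outcome records
    and "Gestation period, X weeks" records, a pregnancy progression
    signature (PPS) algorithm based on temporal compatibility of
    gestationally timed concepts, an estimated start date (ESD) algorithm
    fusing week-level and ranged timing evidence with outlier filtering,
    episode merging with outcome concordance scoring, and COVID-19 cohort
    annotation. Ships a seeded synthetic cohort generator with known
    ground-truth pregnancies so every stage is testable without access to
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
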