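Package: ncdprior
Title: Multi-Criteria Priority Setting for WHO NCD Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gap analysis and multi-criteria prioritization of the WHO menu
    of actions and interventions for the prevention and control of
    non-communicable diseases. Labels the 105-item menu against national
    policy documents, derives criterion weights from expert pairwise
    comparison matrices by the analytic hierarchy process with
    consistency-ratio checking, scores preventable hospitalization from
    ICD-10 inpatient claims through the "4 diseases, 4 shared risk
    factors" model, and produces distributive-mode weighted-sum rankings
    of the risk-factor and clinical intervention sets. Includes a
    synthetic-data generator so the whole pipeline is testable without
    access to the original national data sources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
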