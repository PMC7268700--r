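Package: hospexp
Title: Multi-Agent Simulation of Medical Expense Growth in a Tiered
    Public-Hospital System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time multi-agent simulator of how medical expenses
    arise in a three-level public-hospital system (community health service
    centers, district hospitals, specialized and tertiary comprehensive
    hospitals). Patient agents are generated per two-week cycle from disease
    prevalences, demographics and district population densities; they choose
    an institution type by severity-, age- and income-dependent preference
    weights modulated by government promotion of the community first-visit
    system, and are assigned the nearest facility of that type. Doctor agents
    over-prescribe with a probability set by the gap between expected income
    (a linear function of weekly workload) and actual income, damped by the
    institution's public-welfare responsibility index, which rises with
    government subsidies. An expense engine prices each episode from a
    per-disease, per-institution schedule with compounded annual growth,
    over-prescription inflation of medicine and physical-examination
    components, and insurance-reimbursement-driven prescription adherence.
    Includes a seeded synthetic parameter generator, ten policy-intervention
    scenario presets, annual Table-style summaries, and a +/-10 percent
    validation protocol against observed yearbook series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
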