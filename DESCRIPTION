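Package: navsim
Title: Microsimulation Cost-Effectiveness Analysis of Breast Cancer
    Screening Navigation Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level (microsimulation) model of breast cancer
    natural history, mammography screening, and downstream economics, built
    to evaluate community patient-navigation programs that raise screening
    uptake in underserved populations. Simulates annual-cycle life courses
    from cohort entry to death under alternative screening policies with
    common random numbers, accrues discounted lifetime costs and
    quality-adjusted life years, computes incremental cost-effectiveness
    ratios against a willingness-to-pay threshold, constructs two-way
    program-cost by screening-rate cost-effectiveness frontiers, and
    calibrates free model parameters to published per-arm outcomes by
    derivative-free search with exact profiling of linearly entering
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
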