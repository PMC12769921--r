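Package: aaadcea
Title: Distributional Cost-Effectiveness Analysis of Abdominal Aortic
    Aneurysm Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level discrete event simulation of abdominal aortic
    aneurysm (AAA) natural history and the one-off invitation to ultrasound
    screening offered to 65-year-old men in England, stratified by Index of
    Multiple Deprivation quintile, together with the distributional
    cost-effectiveness analysis (DCEA) built on top of it: health opportunity
    cost and its socioeconomic distribution, per-quintile net health benefit,
    counterfactual quality-adjusted life expectancy, Atkinson
    equally-distributed-equivalent health, threshold inequality aversion, and
    equal-opportunity-cost and leveling-up scenario analyses. Registry and
    national-statistics inputs that cannot be redistributed are emulated by
    documented synthetic generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
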