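Package: cyclebreakeven
Title: Break-Even Appraisal of Cycling Infrastructure Investment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Health-economic appraisal of cycling infrastructure using a
    transparent comparative risk assessment model in the style of the WHO
    Health Economic Assessment Tool (HEAT). Values a change in the
    population distribution over five cycling-frequency levels across four
    domains (physical-activity mortality, air-pollution exposure, crash
    risk, carbon emissions) in international dollars via the value of a
    statistical life, solves for the population shift to regular cycling at
    which discounted benefits exactly offset construction cost (benefit-cost
    ratio 1:1), and runs one-way deterministic sensitivity analyses. Ships
    the Coventry 6-km separated-cycleway case study as a built-in fixture
    together with a generator of randomised valid configurations for
    property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
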