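Package: ibuvbe
Title: Physiologically Based Biopharmaceutics Modeling and Virtual
    Bioequivalence for Immediate-Release Ibuprofen Tablets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic workflow for immediate-release racemic ibuprofen
    tablets: a diffusion layer model (DLM) of polydisperse particle
    dissolution whose surface solubility is governed by particle surface pH,
    fitted to staged in vitro dissolution protocols; a compartmental
    gastrointestinal absorption model coupled to per-enantiomer disposition
    with unidirectional R-to-S chiral inversion; virtual populations with
    between- and within-subject variability; crossover bioequivalence
    statistics (geometric mean ratio, 90% confidence interval, two one-sided
    tests, variance components, sample size); Morris elementary-effects
    sensitivity screening; and safe-space mapping plus replicated virtual
    bioequivalence campaigns.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
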