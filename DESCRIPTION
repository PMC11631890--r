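Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling for First-Line
    Therapy in Advanced Cervical Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioned survival cost-effectiveness analysis of
    atezolizumab plus bevacizumab and chemotherapy versus bevacizumab and
    chemotherapy in metastatic, persistent or recurrent cervical cancer, from
    the perspective of US healthcare payers. Includes reconstruction of
    pseudo individual patient data from digitized Kaplan-Meier curves with
    numbers at risk, parametric and flexible (Royston-Parmar spline,
    restricted cubic spline, fractional polynomial, piecewise exponential)
    survival fitting and extrapolation with AIC/BIC model selection, a
    three-state (progression-free, progressed, dead) partitioned survival
    model with half-cycle correction and discounting, and deterministic
    (one-way, tornado) and probabilistic (Monte Carlo, acceptability curve)
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    flexsurv,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
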