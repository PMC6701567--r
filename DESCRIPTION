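Package: quitcea
Title: Cost-Effectiveness Analysis of Smoking-Cessation Programmes with a
    Lifetime Markov Cohort Model
Version: 0.1.0
Authors@R:
    person("quitcea", "maintainers", email = "maintainers@quitcea.org",
           role = c("aut", "cre"))
Description: Tools for the economic evaluation of high- versus low-intensity
    smoking-cessation treatment (HIT vs LIT). Implements a lifetime Markov
    cohort model of smoking-attributable disease (lung cancer, COPD, CHD,
    stroke) with age- and sex-specific excess incidence that decays after
    quitting, discounted societal costs and quality-adjusted life-years
    (QALYs); an incremental cost-effectiveness layer (ICER, dominance);
    a logistic model of sustained abstinence with odds ratios and
    parameter-recovery simulation; and a probabilistic sensitivity analysis
    over the HIT quit rate with cost-effectiveness acceptability curves.
    Ships transcriptions of the trial's published summary tables as
    plain-text fixtures and a synthetic-parameter generator so the whole
    pipeline is testable without access to the unpublished national
    parameter report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
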