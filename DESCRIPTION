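Package: riskcalib
Title: Discrimination, Calibration, and Reliability Validation for
    Actuarial Violence-Risk Instruments
Version: 0.1.0
Authors@R:
    person("Riskcalib", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to validate actuarial violence-risk assessment
    instruments such as the Violence Risk Appraisal Guide-Revised
    (VRAG-R) against an external cohort: item-weight scoring with
    proration of omitted items and nine-bin risk categorisation;
    rank-based discrimination (Mann-Whitney AUC with Hanley-McNeil
    confidence intervals and the small/medium/large effect ladder);
    calibration via logistic score-to-rate models, Hosmer-Lemeshow
    goodness of fit, and the expected/observed (E/O) index with
    multiplicative 95 percent confidence intervals; an interrater and
    internal-consistency battery (one-way and two-way intraclass
    correlations, unweighted and weighted Cohen's kappa, Gwet's AC1/AC2,
    percent agreement, Cronbach's alpha); descriptive and comparative
    cohort statistics (Welch t with Cohen's d, chi-square with Cramer's
    V, fixed follow-up outcome construction); and a seeded
    synthetic-cohort generator that emulates a forensic
    not-criminally-responsible population so the whole pipeline is
    testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
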