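Package: noisymeasures
Title: Cost-Effectiveness of Cheaper-but-Noisier Outcome Measures in Large
    Simple Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for deciding when a cheap-but-noisy outcome
    measure (such as a short questionnaire) is more cost-effective than a
    gold-standard measure in a large simple trial. Computes the variance from
    outcome categorisation for uniform and constrained discrete normal outcome
    distributions, the two-arm normal-approximation sample size and the
    analytic cost-effectiveness decision rule, a random-effects log-log
    meta-regression of response odds on questionnaire length (the participant
    burden power law), and an illustrative cost-ratio simulation over outcome
    standard deviations and category counts, with and without a non-response
    penalty.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    metafor,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
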