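Package: csgprev
Title: Cost-Effectiveness of Cancer Risk-Reducing Strategies for Cancer
    Susceptibility Gene Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model for evaluating ovarian and
    breast cancer risk-reduction strategies (risk-reducing
    salpingo-oophorectomy, risk-reducing mastectomy, breast surveillance and
    medical prevention) in women carrying pathogenic variants in BRCA1, BRCA2,
    PALB2, RAD51C, RAD51D or BRIP1. Annual-cycle cohort simulation over ages
    30-100 with tunnel states for the first ten years after a cancer
    diagnosis, age-adjusted utilities, UK payer-perspective costs and 3.5%
    discounting. Provides incremental cost-effectiveness ratios, net monetary
    benefit, cost-effectiveness frontiers, cancer cases and deaths prevented
    per 1000 carriers, one-way and probabilistic sensitivity analyses with
    cost-effectiveness acceptability curves, scenario analyses, and a
    synthetic parameter-set generator calibrated to published lifetime risks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
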