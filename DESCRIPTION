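Package: dermabs
Title: Default Dermal Absorption Values from In Vitro Study Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives regulatory default values for dermal absorption of
    plant-protection products from harmonised in vitro study records.
    Implements the preprocessing rules (mass-balance recovery filter,
    tape-strip exclusion, potential absorption), empirical 95th
    percentiles with distribution-free order-statistic upper confidence
    limits, and a Bayesian Gaussian linear mixed model on the logit
    fraction absorbed fitted by a blocked Gibbs sampler, from which
    upper limits of 90% prediction intervals are constructed at three
    levels of random-effect variation. Includes a hierarchical
    synthetic-data generator with known ground truth, a
    concentrate-definition sensitivity analysis (commercial vs. the
    50 g/L cut-off), and a reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
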