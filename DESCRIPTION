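Package: twostageGWAS
Title: Optimal Two-Stage Genome-Wide Association Study Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes cost-minimizing and power-maximizing two-stage
    case-control genome-wide association study designs in which cases and
    controls may be allocated to the stages in different proportions.
    Provides the multiplicative disease model under Hardy-Weinberg
    equilibrium with effect-size calibration to a one-stage power baseline,
    Fisher-information-weighted joint analysis of staged allele-frequency
    tests with numerically calibrated critical values, analytic power by
    bivariate-normal tail integration, constrained grid-search design
    optimization, and Monte Carlo verification including batch-effect
    sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, graphics
Suggests: testthat (>= 3.0.0), optparse, jsonlite, yaml
Config/testthat/edition: 3
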