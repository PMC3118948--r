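Package: nuapower
Title: Non-Uniform Association Models and Power Analysis for Ordinal
    Agreement Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits log-linear uniform-association (UA) and non-uniform
    association (NUA) models to square contingency tables arising when the
    same objects are rated twice on an ordinal scale, estimates
    Darroch-McCloud degrees of distinguishability between scale categories,
    and tests homogeneity of adjacent-category distinguishability with
    likelihood-ratio (G-squared) tests. Includes an exact multinomial table
    simulator with controlled marginal distributions, a Monte-Carlo engine
    estimating power and type-I error of UA-versus-NUA tests over grids of
    odds ratios and sample sizes, and interpolation utilities for
    required-sample-size calculations from tabulated power estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
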