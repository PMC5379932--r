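Package: ebshrink
Title: Adaptive Shrinkage and False Sign Rates by Empirical Bayes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Empirical Bayes shrinkage estimation and significance testing for
    large collections of effect estimates with standard errors. Fits a unimodal
    mixture prior (point mass plus normal, uniform or half-uniform components on
    a fixed grid of scales) to pairs (betahat, sebetahat) by penalized maximum
    likelihood, and returns per-effect local false discovery rates, local false
    sign rates, shrinkage point and interval estimates, and s- and q-values.
    Includes a simulation harness for null-proportion calibration,
    credible-bound coverage and precision-contamination experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
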