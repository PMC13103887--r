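Package: chronodiag
Title: Diagnostics for Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic tools for dated (time-calibrated) phylogenies in microbial
    population genetics. Given a dated tree and the substitution-scaled tree it was
    inferred from, detects inference problems via outlier detection (root-to-tip
    regression with an expected envelope, date randomization, per-branch tests),
    posterior predictive checks on tree summary statistics, and randomized
    probability-integral-transform residual analysis with an Anderson-Darling
    simple-hypothesis test. Includes four molecular clock models (strict and
    additive relaxed, discrete and continuous), a Bayesian dating engine with a
    heterochronous coalescent prior, a pseudo-posterior sampler for point-estimate
    dated trees, and coalescent simulators (constant and time-varying population
    size, clonal expansion, population structure) to generate test data.
License: MIT
Encoding: UTF-8
Depends: R (>= 3.5)
Imports: ape, stats, utils
Suggests: testthat (>= 3.0.0), phangorn, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
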