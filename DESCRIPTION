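Package: cortinterp
Title: Polynomial Interpolation of Sparsely Sampled 24-Hour Cortisol Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for optimizing polynomial interpolation of sparsely
    sampled 24 h serum and salivary cortisol profiles. Implements the
    canonical equidistant and intermittent sampling schemes (Q60 through
    Q360, INT1, INT2) with their maximum permitted polynomial degrees,
    per-profile polynomial validation across degrees, stochastic
    interpolation that injects residual-bounded truncated-Gaussian error
    over 100 seeded replicates summarized by kernel-density peaks,
    estimation of 24 h hormone output by trapezoidal integration, and
    paired two one-sided tests (TOST) of equivalence alongside a two-way
    ANOVA of ground-truth output. A seeded synthetic circadian-cortisol
    cohort generator provides realistic serum/saliva profiles (two-harmonic
    cosinor plus an exercise transient) so the full pipeline can be
    exercised and tested without access to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
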