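Package: ffproteo
Title: Random-Forest Biomarker Discovery for Follicular-Fluid Proteomics
Version: 0.1.0
Authors@R: person("ffproteo", "Maintainers", email = "maintainers@ffproteo.dev",
    role = c("aut", "cre"))
Description: Statistical machinery for two-group differential analysis of
    label-free (SWATH-MS style) protein abundance matrices with a nested
    repeated-measures design (patient > follicular fluid > technical repeat),
    as used in PCOS biomarker discovery.  Provides class-weighted,
    capacity-limited random forests scored by Gini impurity, grouped k-fold
    recursive feature elimination with cross-validation (RFECV) and
    persistence-score accumulation, bootstrap difference-in-medians log2
    fold-change estimation with pseudoreplication-safe aggregation,
    winsorised robust correlation, and a synthetic cohort simulator so the
    whole pipeline can be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
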