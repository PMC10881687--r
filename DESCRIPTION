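Package: bycatchsim
Title: Missing-Data Sensitivity Analysis for Mitogenome Bycatch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates patchy haploid mitogenome alignments from a structured
    heterochronous coalescent with migration and GTR+Gamma sequence evolution,
    and quantifies how coverage breadth (the proportion of reference positions
    with a called base) distorts downstream evolutionary inference. Implements
    coverage-breadth filtering into threshold datasets, a from-scratch
    Discriminant Analysis of Principal Components (DAPC) with mean imputation
    and admixture classification, a heterochronous coalescent likelihood with
    classic and Bayesian skyline estimators of effective population size
    through time, distance-based dated tree estimation under pairwise
    deletion, and a monophyly-proportion statistic over posterior tree sets.
    A pipeline orchestrates the full experiment: simulate, mask, threshold,
    analyse per threshold, and summarise coverage-driven artefacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
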