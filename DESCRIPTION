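Package: introsweep
Title: Adaptive Gene Introgression and Hitchhiking After a Single Hybridization Event
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and simulation machinery for the introgression of a
    beneficial allele that enters a resident haploid population on a hybrid
    haplotype together with linked and unlinked deleterious alleles. Provides
    a recursive solver for the establishment (introgression) probability based
    on a reducible multitype branching process, a two-phase calculator
    (stochastic rescue phase plus semi-deterministic sweep phase) for the
    probability that deleterious alleles hitchhike to fixation, and an exact
    Moran-model Monte-Carlo simulator with recombination that serves as a
    ground-truth oracle for the analytic approximations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
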