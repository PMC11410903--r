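Package: targetmr
Title: Drug-Target and Clustered Mendelian Randomization with Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-target (cis) and genome-wide Mendelian
    randomization from GWAS summary statistics: instrument selection under
    p-value and linkage-disequilibrium pruning rules, allele harmonization
    with proxy substitution, Wald-ratio, inverse-variance-weighted,
    weighted-median and MR-Egger causal estimators (including generalized
    weighted least squares for LD-correlated instruments), approximate
    Bayes factor colocalization with hypothesis posteriors, EM-fitted
    Gaussian mixture clustering of variant-level causal estimates with null
    and junk components, cross-study meta-analysis with heterogeneity-driven
    model selection, and a synthetic summary-statistics generator with known
    truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
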