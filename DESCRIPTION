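Package: metabosig
Title: Metabolic Signature Discovery for Untargeted DI-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating plasma-metabolomics
    classification models and metabolite signatures from direct-infusion
    mass-spectrometry peak tables. Provides a synthetic cohort generator
    with repeated visits, technical replicates, batch shifts and
    intensity-dependent missingness; peak-table preprocessing (missingness
    filtering, quantile normalisation, autoscaling, batch centering,
    replicate averaging); subject-grouped stratified cross-validation
    including a dual-variable scheme for treatment-confounded phenotypes;
    random-forest classification with permuted-label negative controls,
    DeLong ROC comparison and bootstrap subset tests; univariate V-score
    and logistic-Wald feature ranking; permutation-based signature
    thresholding with elbow detection; and mummichog-style metabolite-set
    enrichment with adduct expansion, EASE scoring and construction of
    microbe-association metabolite-set databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
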