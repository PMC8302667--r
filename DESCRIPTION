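Package: qdrisk
Title: Quantitative Disease Risk Scores from EHR Phenotype Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds phecode presence matrices from longitudinal
    code-occurrence records and derives quantitative disease risk scores:
    the inverse-prevalence phenotype risk score (PheRS), the
    utilization-normalized denoising score (PheNorm), and an
    eigenvalue-weighted linear combination of principal components (LPC)
    with Tracy-Widom selection of the number of components.  Includes
    score evaluation (AUROC, AUPRC, Spearman correlation with ordinal
    disease staging, percentile-bin case prevalence, weight-enrichment
    tests), polygenic-risk-score driven pre-selection of phecodes, and
    gene-based association of the quantitative scores with sequencing
    variants: Beta(1,25)-weighted burden and dispersion score tests,
    ultra-rare variant aggregation, single-variant score tests, and
    aggregated Cauchy combination, under Gaussian or inverse-Gaussian
    null models adjusted for covariates.  A synthetic EHR and genotype
    cohort generator makes every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
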