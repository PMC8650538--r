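Package: popgrs
Title: Population-Level Comparison of Polygenic and Clinical Coronary Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing coronary artery disease risk between two
    populations at biobank scale: unweighted and weighted genetic risk scores
    from risk-allele dosages with expected-value imputation of missing
    genotypes, sex-stratified Cox-survival 10-year risk scores (Framingham
    lipid and BMI models) evaluated from declarative coefficient
    specifications, per-SNP risk-allele-frequency scans with Bonferroni
    correction, and the standard two-sample tests (Pearson chi-squared,
    Welch t, Mann-Whitney, Kolmogorov-Smirnov). Includes a synthetic cohort
    generator (Hardy-Weinberg genotypes with planted allele-frequency
    differences, phenotype profiles, and a calibrated logistic disease
    model) so the full pipeline is testable without access-controlled data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    ggplot2,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
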