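Package: eprs
Title: Ancestry-Aware Calibration of Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the expected polygenic risk score (ePRS) of an
    individual from their ancestral makeup -- either genome-wide (global)
    ancestry proportions or per-locus, per-haplotype (local) ancestry calls --
    together with the residual PRS (rPRS), the model-based PRS variance, and
    the quantile PRS (qPRS), a person-specific percentile of the PRS within
    the distribution implied by the individual's admixture pattern. Adjusting
    PRS-outcome association models for the ePRS protects against population
    stratification bias without genetic principal components. Includes a
    simulator of admixed cohorts with ancestry-correlated genetic confounders,
    the suite of working association models used to study estimator bias and
    mean squared error, readers and writers for the common tabular formats
    (PGS-Catalog scoring files, ancestry-specific allele-frequency panels,
    ADMIXTURE-style Q tables, RFMix msp local-ancestry calls, VCF and dosage
    matrices), and ggplot2 visualisations of the results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    yaml
Config/testthat/edition: 3
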