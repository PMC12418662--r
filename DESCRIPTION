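Package: metabocontrast
Title: Extreme Metabolomic Health-Score Contrasts with Multi-Omics
    Association and Twin Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects a mortality-trained metabolomic health score
    (a weighted sum of 14 log-transformed, per-cohort z-scaled NMR
    analytes), selects score extremes with age- and sex-matched controls
    in population cohorts and the most score-discordant monozygotic twin
    pairs in a twin registry, preprocesses cytokine panels (left-censored
    detectability analysis with Fisher exact tests, undetected-fraction
    filtering, outlier masking) and plasma proteomics (missingness
    filtering, NIPALS missing-value imputation), and runs
    covariate-adjusted linear association scans with Benjamini-Hochberg
    correction, cross-cohort REML random-effects meta-analysis,
    within-pair linear mixed models, and Falconer twin heritability.
    Ships a synthetic multi-cohort generator with a latent health trait
    of tunable heritability so the whole pipeline is testable without
    access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
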