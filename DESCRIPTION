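Package: flymetab
Title: Lifespan, Metabolic Flux and Transcriptome Analysis for Drosophila
    Tauopathy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for Drosophila neurodegeneration
    and aging studies: Gompertz decomposition of lifespan into baseline
    mortality and aging rate with kernel-smoothed hazard diagnostics and
    pairwise Wald z-tests; pH-corrected ratiometric ATP/ADP (PercevalHR)
    trace analysis with counterfactual-baseline integrated change;
    random-intercept linear mixed models for Seahorse extracellular flux
    metrics (glycolytic reserve, 2DG decline slope, ATP-linked respiration,
    respiratory reserve, peak capacity); and a transcriptome summary layer
    (TPM, PCA/k-means QC, dual-control DEG concordance, Fisher
    over-representation scoring, 2^-ddCt). Synthetic-data generators with
    the statistical structure each stage assumes make the full pipeline
    testable without raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    lme4,
    lmerTest,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    withr,
    emmeans
Config/testthat/edition: 3
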