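Package: desiccatome
Title: Differential Abundance Analysis for Dehydration-Rehydration
    Transcriptome and Metabolome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing gene expression and
    metabolite abundance across a dehydration-rehydration series in
    desiccation-tolerant plants. Provides RMA-style probe summarisation
    (quantile normalisation and median polish), a replicate-cleansing rule for
    triplicate expression values based on the coefficient of variation and
    standardised deviations, one-way ANOVA with Benjamini-Hochberg FDR control
    and Tukey-Kramer post-hoc calling of significantly differentially abundant
    transcripts, average-pairwise-Pearson threshold clustering of expression
    profiles, Welch's t-test metabolite ratio tables with rehydration
    trajectory classification, delta-delta-Ct qPCR concordance analysis,
    internal-standard calibration-curve quantification of abscisic acid, and
    hypergeometric gene-set enrichment. A synthetic-data generator with
    planted ground truth drives the whole analysis without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
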