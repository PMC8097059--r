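Package: kinasesig
Title: Differential Phosphoproteomics, Kinase Activity Signatures and Drug
    Synergy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative (phospho)proteomics
    differential analysis and downstream kinase-activity inference.
    Implements SAM-style moderated two-class tests with an additive fudge
    factor s0 and permutation-based FDR, one-way ANOVA and one-sample
    moderated t tests with Benjamini-Hochberg correction, volcano-plot
    prioritization with asymmetric 3xSD fold-change thresholds,
    proteome-level correction and functional-score filtering,
    kinase-substrate enrichment analysis (KSEA) with predicted-edge network
    expansion, cross-comparison kinase signature construction with k-means
    clustering, Fisher-exact over-representation analysis, ranked up/down
    signature queries scored by an unweighted Kolmogorov-Smirnov
    connectivity statistic, four-parameter logistic dose-response fitting
    with IC50 comparison, and Bliss-independence drug-synergy scoring.
    Ships a synthetic-data generator with known ground truth so every stage
    is verifiable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
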