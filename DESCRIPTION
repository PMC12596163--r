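Package: ecnorm
Title: Context-Stable Endogenous Control Selection and In Silico PCR
    Normalization for RNA-seq and miRNA-seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: From a raw NGS count matrix and a two-group sample metadata
    table, estimates median-of-ratios size factors, fits per-gene negative
    binomial generalized linear models with a Wald test for differential
    expression, selects differentially expressed biomarkers and
    context-stable endogenous controls by stability filters on fold change,
    p-value and dispersion, and validates candidate controls by in silico
    qPCR/ddPCR normalization (per-sample biomarker/control count ratios
    with Wilcoxon rank-sum tests). Includes a negative binomial count
    simulator with planted stable and differentially expressed genes, plot
    helpers (heatmap, volcano, ratio boxplots), a scriptable end-to-end
    pipeline and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    MASS,
    rlang,
    grid,
    jsonlite,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
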