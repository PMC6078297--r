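Package: motifanova
Title: Detection of Three-Gene Regulatory Network Motifs by Factorial ANOVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and discriminates three-gene regulatory network motifs
    (cascade chains, feed-forward loops, and dense-overlapping regulons) from
    replicated gene-expression data. The core method decomposes a three-way
    factorial ANOVA design built from the expression profiles of two
    transcription factors and a target gene into eight sum-of-squares terms
    and classifies motif pairs by cross-validated products and ratios of
    normalized terms. Pairwise and conditional baselines (Pearson, Spearman,
    mutual information, partial correlation, conditional mutual information,
    two-way ANOVA eta-squared), motif enumeration from gold-standard edge
    lists, synthetic expression generators with embedded labeled motifs, and
    AUROC/AUPR ranking evaluation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    nortest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
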