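Package: gcoex
Title: Gene Co-Expression Network Construction, Module Detection, and
    Guilt-by-Association Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Command-line style toolkit for building gene co-expression
    networks from RNA-Seq expression matrices and annotating genes of
    unknown function (in particular long non-coding RNAs) by guilt by
    association.  Provides five expression normalization methods (median,
    quantile, median-of-ratios, trimmed mean of M-values, housekeeping
    genes), low-expression gene filtering, all-pairs Spearman/Pearson
    correlation networks with p-value and false discovery rate control,
    module identification by shared-neighbour node similarity coupled with
    average-linkage hierarchical clustering, hypergeometric enrichment of
    neighbour or module annotations, random walk with restart network
    propagation, a degree-preserving shuffled-network control, and a
    leave-one-out accuracy evaluator.  All stages are exposed both as R
    functions and as subcommands of a single command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DESeq2,
    edgeR,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
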