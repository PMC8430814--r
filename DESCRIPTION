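Package: mirtarnet
Title: Integrated miRNA-mRNA Inverse-Correlation Network Analysis of Drug
    Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying microRNA-regulated genes involved in
    acquired drug resistance from paired miRNA and gene expression
    microarray data.  Implements per-clone differential-expression calling
    (fold-change and Benjamini-Hochberg FDR thresholds), mapping of
    differentially expressed features onto a validated miRNA:target
    reference network, inverse-correlation filtering, intersection of
    resistant clones into common resistance networks, hypergeometric
    over-representation analysis against GMT gene-set collections,
    four-parameter logistic dose-response (IC50) estimation for MTT
    viability assays, and delta-Ct relative quantification for qPCR.
    Includes a synthetic-data generator that plants known miRNA->gene
    repression pairs so the full pipeline can be benchmarked for precision
    and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
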