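Package: nfkbtargets
Title: Transcription Factor Target Genes from Differential Expression and
    ChIP-Seq Binding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies transcription-factor target genes among
    differentially expressed genes by combining microarray-style expression
    analysis with ChIP-Seq peak calls. Provides quantile normalization,
    per-gene two-sample t tests with Benjamini-Hochberg false discovery
    rate control, hypergeometric over-representation analysis against gene
    set collections, promoter-window (1 kb) assignment of binding peaks to
    genes, directional Fisher exact enrichment of binding among up- and
    downregulated genes, and target-fraction summaries. Includes a
    synthetic-data generator with known ground truth (differential
    expression status, bound promoters, true binding odds ratio) so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma
biocViews: GeneExpression, DifferentialExpression, ChIPSeq,
    GeneSetEnrichment, Transcription, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
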