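#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors mcols mcols<-
NULL

#' ExpressionTable: a feature-by-sample intensity matrix with group labels
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one assay (`"exprs"`), a per-sample `group` factor in `colData`, and a
#' scale marker (`"linear"` or `"log2"`) in `metadata`. Downstream testing
#' requires exactly two groups; the first factor level is the reference
#' "group A" (the fetal analogue in the motivating study), so positive
#' differences mean higher expression in group A.
#'
#' @name ExpressionTable-class
#' @aliases ExpressionTable-class
#' @exportClass ExpressionTable
setClass("ExpressionTable", contains = "SummarizedExperiment")

setValidity("ExpressionTable", function(object) {
    msg <- character()
    v <- SummarizedExperiment::assay(object, "exprs")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "feature and sample IDs are required (dimnames)")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, sprintf("duplicate feature ID: '%s'",
                                  rownames(v)[duplicated(rownames(v))][1L]))
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, sprintf("duplicate sample ID: '%s'",
                                  colnames(v)[duplicated(colnames(v))][1L]))
    }
    if (!is.numeric(v))
        msg <- c(msg, "values must be numeric")
    else if (length(v) && !all(is.finite(v)))
        msg <- c(msg, "all values must be finite")
    sc <- S4Vectors::metadata(object)$scale
    if (is.null(sc) || !sc %in% c("linear", "log2"))
        msg <- c(msg, "metadata scale marker must be 'linear' or 'log2'")
    else if (identical(sc, "linear") && length(v) && any(v <= 0))
        msg <- c(msg, "linear-scale values must be strictly positive")
    g <- SummarizedExperiment::colData(object)$group
    if (is.null(g) || anyNA(g))
        msg <- c(msg, "every sample needs a group label")
    if (length(msg)) msg else TRUE
})

#' DEResults: per-feature differential expression statistics
#'
#' A [S4Vectors::DFrame] subclass with one row per feature (probe or gene)
#' and columns `mean_A`, `mean_B`, `diff` (= mean_A - mean_B, log2 units),
#' `t_stat`, `df`, `p_value`, `q_value` (Benjamini-Hochberg), `direction`
#' ("up" = higher in group A), `is_de` (strict q < threshold), and
#' `zero_variance`. Gene-level tables produced by [collapseProbesToGenes()]
#' additionally carry an `ambiguous` column. The FDR threshold, group
#' labels and bookkeeping counts live in `metadata()`.
#'
#' @name DEResults-class
#' @aliases DEResults-class
#' @exportClass DEResults
setClass("DEResults", contains = "DFrame")

setValidity("DEResults", function(object) {
    need <- c("mean_A", "mean_B", "diff", "t_stat", "df", "p_value",
              "q_value", "direction", "is_de")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    if (nrow(object)) {
        if (any(object$q_value < object$p_value - 1e-12, na.rm = TRUE))
            return("q_value must be >= p_value")
        if (any(object$q_value < 0 | object$q_value > 1, na.rm = TRUE))
            return("q_value must lie in [0, 1]")
        if (!all(object$direction %in% c("up", "down")))
            return("direction must be 'up' or 'down'")
    }
    TRUE
})

#' GeneSetCollection: named gene sets with optional descriptions
#'
#' @slot sets named list of character vectors (deduplicated gene IDs,
#'   first-seen order preserved).
#' @slot descriptions character vector parallel to `sets`.
#' @name GeneSetCollection-class
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (length(object@sets) && (is.null(nm) || any(!nzchar(nm))))
        msg <- c(msg, "every gene set needs a name")
    if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicate set name: '%s'",
                              nm[duplicated(nm)][1L]))
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "descriptions must parallel sets")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "within-set gene IDs must be deduplicated")
    if (length(msg)) msg else TRUE
})

#' EnrichmentResults: over-representation analysis results
#'
#' A [S4Vectors::DFrame] subclass, one row per tested gene set, with columns
#' `set_name`, `k` (overlap), `n` (study-list size), `K` (set size within
#' background), `N` (background size), `fold_enrichment`, `p_value`
#' (hypergeometric upper tail), `q_value` (BH across tested sets) and
#' `significant`. Rows are sorted by q then decreasing fold enrichment.
#'
#' @name EnrichmentResults-class
#' @aliases EnrichmentResults-class
#' @exportClass EnrichmentResults
setClass("EnrichmentResults", contains = "DFrame")

setValidity("EnrichmentResults", function(object) {
    need <- c("set_name", "k", "n", "K", "N", "fold_enrichment",
              "p_value", "q_value")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    if (nrow(object)) {
        bad <- object$k > pmin(object$n, object$K) |
            pmin(object$n, object$K) > object$N | object$k < 0
        if (any(bad))
            return("counts must satisfy 0 <= k <= min(n, K) <= N")
    }
    TRUE
})

#' TargetEnrichmentResults: per-subunit, per-direction binding enrichment
#'
#' A [S4Vectors::DFrame] subclass with one row per (subunit, direction)
#' combination: the 2x2 table cells `a` (DE & bound), `b` (DE & unbound),
#' `c` (non-DE & bound), `d` (non-DE & unbound), the sample odds ratio
#' `odds_ratio` = (a*d)/(b*c) with 0/Inf sentinels, the conditional-MLE
#' `or_cmle`, the two-sided Fisher `p_value`, the integer `fraction_pct`
#' (= 100*a/(a+b), half-up), and a `target_genes` list column holding the
#' a-cell gene IDs.
#'
#' @name TargetEnrichmentResults-class
#' @aliases TargetEnrichmentResults-class
#' @exportClass TargetEnrichmentResults
setClass("TargetEnrichmentResults", contains = "DFrame")

setValidity("TargetEnrichmentResults", function(object) {
    need <- c("subunit", "direction", "a", "b", "c", "d", "odds_ratio",
              "p_value", "fraction_pct", "target_genes")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    if (nrow(object)) {
        if (any(lengths(object$target_genes) != object$a))
            return("|target_genes| must equal the a cell")
        if (any(object$fraction_pct < 0 | object$fraction_pct > 100,
                na.rm = TRUE))
            return("fraction_pct must lie in [0, 100]")
    }
    TRUE
})
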