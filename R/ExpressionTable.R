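#' Construct an ExpressionTable
#'
#' @param values numeric matrix, features x samples, with unique row and
#'   column names.
#' @param groups sample-to-group assignment: either a named character
#'   vector (names = sample IDs) or a two-column data.frame
#'   (`sample_id`, `group`). Group level order is first-seen order; the
#'   first level is "group A" (higher expression there is reported as
#'   direction "up").
#' @param scale `"log2"` (default) or `"linear"`. Linear intensities must
#'   be strictly positive and are typically passed through
#'   [quantileNormalize()] and [log2Transform()] before testing.
#' @return An [ExpressionTable-class] object.
#' @examples
#' m <- matrix(rnorm(8, 7), 4, 2,
#'             dimnames = list(paste0("g", 1:4), c("s1", "s2")))
#' et <- ExpressionTable(m, c(s1 = "fetal", s2 = "adult"))
#' et
#' @export
ExpressionTable <- function(values, groups, scale = c("log2", "linear")) {
    scale <- match.arg(scale)
    if (!is.matrix(values))
        values <- as.matrix(values)
    if (is.data.frame(groups)) {
        if (ncol(groups) < 2L)
            stop("groups data.frame needs columns sample_id and group")
        g <- stats::setNames(as.character(groups[[2L]]),
                             as.character(groups[[1L]]))
    } else {
        g <- groups
    }
    sids <- colnames(values)
    if (is.null(sids))
        stop("values must have sample IDs as column names")
    missing <- setdiff(sids, names(g))
    if (length(missing))
        stop(sprintf("sample '%s' has no group label", missing[1L]))
    extra <- setdiff(names(g), sids)
    if (length(extra))
        stop(sprintf("group label for unknown sample '%s'", extra[1L]))
    gl <- as.character(g[sids])
    grp <- factor(gl, levels = unique(gl))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(group = grp, row.names = sids),
        metadata = list(scale = scale))
    methods::new("ExpressionTable", se)
}

#' @rdname ExpressionTable
#' @param x an `ExpressionTable`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname ExpressionTable
#' @export
sampleGroups <- function(x) {
    g <- SummarizedExperiment::colData(x)$group
    names(g) <- colnames(x)
    g
}

#' @rdname ExpressionTable
#' @export
valueScale <- function(x) S4Vectors::metadata(x)$scale

#' @rdname ExpressionTable
#' @export
featureIds <- function(x) rownames(x)

#' @rdname ExpressionTable
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "ExpressionTable", function(object) {
    g <- sampleGroups(object)
    cat(sprintf("ExpressionTable: %d features x %d samples (%s scale)\n",
                nrow(object), ncol(object), valueScale(object)))
    if (length(g))
        cat("groups:", paste(sprintf("%s (n=%d)", levels(g), table(g)),
                             collapse = ", "), "\n")
})

setMethod("show", "DEResults", function(object) {
    md <- S4Vectors::metadata(object)
    cat(sprintf("DEResults (%s level): %d features, contrast %s - %s\n",
                md$level %||% "probe", nrow(object),
                md$groupA %||% "A", md$groupB %||% "B"))
    cat(sprintf("DE at q < %s: %d up, %d down\n",
                format(md$fdrThreshold %||% 0.05),
                sum(object$is_de & object$direction == "up" &
                        !isTRUE(object$ambiguous)),
                sum(object$is_de & object$direction == "down" &
                        !isTRUE(object$ambiguous))))
    methods::callNextMethod()
})

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n",
                length(object@sets),
                if (length(object@sets))
                    paste(range(lengths(object@sets)), collapse = "-")
                else "-"))
})

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' Gene sets and their descriptions
#'
#' @param x a [GeneSetCollection-class].
#' @return `geneSets()` the named list of member vectors;
#'   `setDescriptions()` the named description vector.
#' @export
geneSets <- function(x) x@sets

#' @rdname geneSets
#' @export
setDescriptions <- function(x) stats::setNames(x@descriptions, names(x@sets))

`%||%` <- function(a, b) if (is.null(a)) b else a
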