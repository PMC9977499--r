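## Differential expression: quantile normalization, log2 transform,
## per-gene pooled-variance Student t test, Benjamini-Hochberg FDR, strict
## q < threshold DE calls, and probe-to-gene collapsing.

#' Quantile normalization
#'
#' Forces every column of the expression matrix onto the identical
#' empirical distribution: the value at rank r in each column is replaced
#' by the mean of the r-th order statistics across columns. Ties within a
#' column receive the average of the reference values over their tied
#' ranks. Idempotent; a single column is returned unchanged.
#'
#' @param x an [ExpressionTable-class] (linear or log2 scale).
#' @return An `ExpressionTable` on the same scale.
#' @examples
#' m <- matrix(c(2, 6, 4, 8), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' et <- ExpressionTable(m, c(s1 = "a", s2 = "b"), scale = "linear")
#' exprValues(quantileNormalize(et))  # both columns become (3, 7)
#' @export
quantileNormalize <- function(x) {
    stopifnot(methods::is(x, "ExpressionTable"))
    v <- exprValues(x)
    if (!all(is.finite(v))) stop("non-finite values in expression matrix")
    if (ncol(v) < 1L) stop("need at least one sample")
    out <- .quantileNormalizeMatrix(v)
    ExpressionTable(out, sampleGroups(x), scale = valueScale(x))
}

.quantileNormalizeMatrix <- function(v) {
    if (ncol(v) == 1L || nrow(v) == 0L) return(v)
    ref <- rowMeans(apply(v, 2L, sort))
    cref <- cumsum(ref)
    out <- apply(v, 2L, function(col) {
        rmin <- rank(col, ties.method = "min")
        rmax <- rank(col, ties.method = "max")
        # mean of ref[rmin:rmax] for each entry, vectorized via cumsums
        (cref[rmax] - c(0, cref)[rmin]) / (rmax - rmin + 1)
    })
    dimnames(out) <- dimnames(v)
    out
}

#' Log2 transform of linear intensities
#'
#' @param x an [ExpressionTable-class] on the linear scale with strictly
#'   positive values.
#' @return An `ExpressionTable` with elementwise log2 values and the scale
#'   marker flipped to `"log2"`.
#' @export
log2Transform <- function(x) {
    stopifnot(methods::is(x, "ExpressionTable"))
    if (!identical(valueScale(x), "linear"))
        stop("log2Transform expects a linear-scale ExpressionTable")
    v <- exprValues(x)
    bad <- which(v <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-positive value at feature '%s', sample '%s'",
                     rownames(v)[bad[1L, 1L]], colnames(v)[bad[1L, 2L]]))
    ExpressionTable(log2(v), sampleGroups(x), scale = "log2")
}

#' Two-sample Student t test (pooled variance)
#'
#' Classical equal-variance two-sided test: pooled variance over
#' `length(a) + length(b) - 2` degrees of freedom. Degenerate zero-variance
#' inputs are kept rather than dropped: equal means give (t = 0, p = 1),
#' unequal means a signed infinite t sentinel with p = 0.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return A list with `t_stat`, `df` and `p_value`.
#' @examples
#' studentTTwoSample(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p ~ 0.0213
#' @export
studentTTwoSample <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 observations")
    if (!all(is.finite(a)) || !all(is.finite(b)))
        stop("non-finite observations")
    r <- .rowStudentT(matrix(a, nrow = 1L), matrix(b, nrow = 1L))
    list(t_stat = r$t[1L], df = r$df[1L], p_value = r$p[1L])
}

## vectorized over matrix rows; the scalar API wraps this
.rowStudentT <- function(ma, mb, varEqual = TRUE) {
    na <- ncol(ma); nb <- ncol(mb)
    mA <- rowMeans(ma); mB <- rowMeans(mb)
    vA <- rowSums((ma - mA)^2) / (na - 1)
    vB <- rowSums((mb - mB)^2) / (nb - 1)
    d <- mA - mB
    if (varEqual) {
        df <- rep.int(na + nb - 2, length(d))
        sp2 <- ((na - 1) * vA + (nb - 1) * vB) / df
        se <- sqrt(sp2 * (1 / na + 1 / nb))
    } else {
        u <- vA / na + vB / nb
        df <- u^2 / (vA^2 / (na^2 * (na - 1)) + vB^2 / (nb^2 * (nb - 1)))
        se <- sqrt(u)
    }
    t <- d / se
    zv <- se == 0
    t[zv & d == 0] <- 0
    t[zv & d > 0] <- Inf
    t[zv & d < 0] <- -Inf
    df[zv] <- na + nb - 2
    p <- 2 * stats::pt(-abs(t), df)
    p[zv & d == 0] <- 1
    p[zv & d != 0] <- 0
    list(t = t, df = df, p = p, meanA = mA, meanB = mB, zeroVar = zv)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")` semantics):
#' with p sorted ascending, q_(i) = min over j >= i of m * p_(j) / j,
#' capped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric())
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression between two groups
#'
#' Runs the pooled-variance Student t test for every feature, adjusts with
#' Benjamini-Hochberg, and calls a feature differentially expressed iff
#' q < `fdrThreshold` (strict). Direction "up" means higher mean in group A
#' (the first group level, the fetal analogue in the motivating design).
#'
#' @param x a log2-scale [ExpressionTable-class] with exactly two groups
#'   and >= 2 samples per group.
#' @param fdrThreshold FDR cutoff, default 0.05 ("FDR < 5\%").
#' @param varEqual classical pooled-variance test (default TRUE); FALSE
#'   switches to the Welch statistic.
#' @return A [DEResults-class] at probe/feature level.
#' @export
runDE <- function(x, fdrThreshold = 0.05, varEqual = TRUE) {
    stopifnot(methods::is(x, "ExpressionTable"))
    if (!identical(valueScale(x), "log2"))
        stop("runDE expects log2-scale values; see log2Transform()")
    if (fdrThreshold <= 0 || fdrThreshold >= 1)
        stop("fdrThreshold must lie in (0, 1)")
    g <- sampleGroups(x)
    if (nlevels(g) != 2L)
        stop(sprintf("exactly two groups required, found %d", nlevels(g)))
    if (any(table(g) < 2L))
        stop("each group needs at least 2 samples")
    v <- exprValues(x)
    a <- v[, g == levels(g)[1L], drop = FALSE]
    b <- v[, g == levels(g)[2L], drop = FALSE]
    r <- .rowStudentT(a, b, varEqual = varEqual)
    q <- bhAdjust(r$p)
    res <- S4Vectors::DataFrame(
        mean_A = r$meanA, mean_B = r$meanB, diff = r$meanA - r$meanB,
        t_stat = r$t, df = r$df, p_value = r$p, q_value = q,
        direction = ifelse(r$meanA - r$meanB > 0, "up", "down"),
        is_de = q < fdrThreshold, zero_variance = r$zeroVar,
        row.names = rownames(v))
    out <- methods::new("DEResults", res)
    S4Vectors::metadata(out) <- list(
        fdrThreshold = fdrThreshold, level = "probe",
        groupA = levels(g)[1L], groupB = levels(g)[2L],
        varEqual = varEqual)
    methods::validObject(out)
    out
}

#' Differentially expressed gene IDs by direction
#'
#' @param x a [DEResults-class].
#' @param direction `"up"`, `"down"` or `"both"`. "up" = higher in group A.
#'   Ambiguous genes (sign-conflicting significant probes after
#'   collapsing) are always excluded.
#' @return Character vector of feature IDs.
#' @export
deGenes <- function(x, direction = c("both", "up", "down")) {
    direction <- match.arg(direction)
    keep <- x$is_de
    if (!is.null(x$ambiguous)) keep <- keep & !x$ambiguous
    if (direction != "both") keep <- keep & x$direction == direction
    rownames(x)[keep]
}

#' Collapse probe-level DE statistics to gene level
#'
#' For each gene, the representative probe is the one with the smallest
#' q-value (ties: smallest p, then lexicographically smallest probe ID);
#' the gene inherits its statistics and direction. Genes whose significant
#' probes disagree in sign are marked `ambiguous` and excluded from the
#' up/down sets returned by [deGenes()]. Probes absent from the map are
#' dropped and counted. BH must already have been applied at probe level
#' (the testing unit), so q-values are inherited, not recomputed.
#'
#' @param x a probe-level [DEResults-class].
#' @param map data.frame with columns `probe_id` and `gene_id`
#'   (many-to-one and one-to-many allowed; duplicate pairs are an error).
#' @return A gene-level [DEResults-class]; `metadata()` records
#'   `nUnmapped` and `ambiguousGenes`.
#' @export
collapseProbesToGenes <- function(x, map) {
    stopifnot(methods::is(x, "DEResults"))
    if (is.null(map) || nrow(map) == 0L)
        stop("probe-to-gene map is empty")
    if (!all(c("probe_id", "gene_id") %in% colnames(map)))
        stop("map needs columns probe_id and gene_id")
    if (anyDuplicated(map[, c("probe_id", "gene_id")]))
        stop("duplicate (probe_id, gene_id) pair in map")
    map <- map[map$probe_id %in% rownames(x), , drop = FALSE]
    nUnmapped <- sum(!rownames(x) %in% map$probe_id)
    if (nUnmapped)
        message(sprintf("collapseProbesToGenes: dropped %d unmapped probe(s)",
                        nUnmapped))
    if (!nrow(map)) stop("no probe in the map matches the DE table")
    idx <- match(map$probe_id, rownames(x))
    ord <- order(map$gene_id, x$q_value[idx], x$p_value[idx], map$probe_id)
    mo <- map[ord, ]; io <- idx[ord]
    first <- !duplicated(mo$gene_id)
    rep_idx <- io[first]
    genes <- mo$gene_id[first]
    res <- methods::as(x[rep_idx, , drop = FALSE], "DFrame")
    rownames(res) <- genes
    ## sign conflicts among *significant* probes of one gene
    sig <- x$is_de[io]
    updn <- (x$direction[io] == "up")
    hasUp <- tapply(sig & updn, mo$gene_id, any)
    hasDn <- tapply(sig & !updn, mo$gene_id, any)
    amb <- names(hasUp)[hasUp & hasDn]
    res$ambiguous <- genes %in% amb
    res$representative_probe <- mo$probe_id[first]
    if (length(amb))
        message(sprintf(
            "collapseProbesToGenes: %d ambiguous gene(s) excluded: %s",
            length(amb), paste(amb, collapse = ", ")))
    out <- methods::new("DEResults", res)
    S4Vectors::metadata(out) <- c(S4Vectors::metadata(x)[
        c("fdrThreshold", "groupA", "groupB", "varEqual")],
        list(level = "gene", nUnmapped = nUnmapped, ambiguousGenes = amb))
    methods::validObject(out)
    out
}
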