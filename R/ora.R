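## Hypergeometric over-representation of a DE gene list in gene-set
## collections, with fold enrichment = (k/n)/(K/N) and BH across the
## tested sets of one run.

#' Hypergeometric upper-tail probability
#'
#' P\[X >= k\] for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least `k` set members when `n` genes are drawn without replacement from
#' a background of `N` genes of which `K` are in the set. Evaluated via
#' `stats::phyper`, which works on log-stable pmf recursions.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K set size within the background.
#' @param n study-list size.
#' @param N background size.
#' @return Upper-tail probability in \[0, 1\].
#' @examples
#' hypergeomUpperTail(4, 5, 4, 10)  # 5/210
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
    if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
        stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Each gene set is intersected with the background; sets whose background
#' size K falls below `minSetSize` are excluded before testing. One
#' upper-tail hypergeometric test per remaining set, BH adjustment across
#' the tested sets only, significance at strict q < `fdrThreshold`.
#' Study-list members outside the background are dropped (counted in
#' `metadata()$nDropped`).
#'
#' @param study character vector of study (e.g. DE) gene IDs.
#' @param collection a [GeneSetCollection-class].
#' @param background character vector: the gene universe (e.g. all genes
#'   on the array / in the DE table).
#' @param minSetSize minimum background-intersected set size (default 2).
#' @param fdrThreshold FDR cutoff for the `significant` flag.
#' @return An [EnrichmentResults-class], sorted by q-value then decreasing
#'   fold enrichment.
#' @export
oraAnalyze <- function(study, collection, background, minSetSize = 2L,
                       fdrThreshold = 0.05) {
    stopifnot(methods::is(collection, "GeneSetCollection"))
    background <- unique(as.character(background))
    if (!length(background)) stop("background is empty")
    study <- unique(as.character(study))
    nDropped <- sum(!study %in% background)
    if (nDropped)
        message(sprintf("oraAnalyze: dropped %d study gene(s) not in background",
                        nDropped))
    study <- study[study %in% background]
    if (!length(study))
        stop("study list is empty after background intersection")
    n <- length(study); N <- length(background)
    rows <- lapply(names(geneSets(collection)), function(nm) {
        members <- intersect(collection[[nm]], background)
        K <- length(members)
        if (K < minSetSize) return(NULL)
        k <- length(intersect(study, members))
        S4Vectors::DataFrame(
            set_name = nm, k = k, n = n, K = K, N = N,
            fold_enrichment = if (k == 0) 0 else (k / n) / (K / N),
            p_value = hypergeomUpperTail(k, K, n, N))
    })
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (!length(rows)) {
        res <- S4Vectors::DataFrame(
            set_name = character(), k = integer(), n = integer(),
            K = integer(), N = integer(), fold_enrichment = numeric(),
            p_value = numeric(), q_value = numeric(),
            significant = logical())
    } else {
        res <- do.call(rbind, rows)
        res$q_value <- bhAdjust(res$p_value)
        res$significant <- res$q_value < fdrThreshold
        res <- res[order(res$q_value, -res$fold_enrichment), , drop = FALSE]
    }
    out <- methods::new("EnrichmentResults", res)
    S4Vectors::metadata(out) <- list(
        nStudy = n, nBackground = N, minSetSize = minSetSize,
        fdrThreshold = fdrThreshold, nDropped = nDropped,
        nSetsTested = nrow(res))
    methods::validObject(out)
    out
}
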