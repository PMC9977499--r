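## The headline computation: assign ChIP-Seq peaks to genes by the 1 kb
## promoter-window rule, test each NF-kB subunit for over/under-
## representation of binding among up- and downregulated genes with an
## exact 2x2 test, define target genes, and summarize target fractions.

#' Assign ChIP-Seq binding to genes (1 kb rule)
#'
#' A gene is called bound if some peak on the same chromosome overlaps the
#' gene interval or lies at a gap of at most `windowBp` bases from it
#' (boundary inclusive); strand is ignored. With `anchor = "tss"` the
#' window is measured from the transcription start site instead of the
#' whole gene body. Implemented as an interval-tree overlap query
#' ([GenomicRanges::findOverlaps] with `maxgap`), equivalent to the
#' quadratic all-pairs check.
#'
#' @param genes named [GenomicRanges::GRanges] of gene models.
#' @param peaks [GenomicRanges::GRanges] of peak calls for one subunit.
#' @param windowBp window in bases, default 1000 ("within 1 kb").
#' @param anchor `"gene"` (gene body, default) or `"tss"`.
#' @return Sorted character vector of bound gene IDs.
#' @export
assignBinding <- function(genes, peaks, windowBp = 1000L,
                          anchor = c("gene", "tss")) {
    anchor <- match.arg(anchor)
    if (windowBp < 0) stop("windowBp must be >= 0")
    if (is.null(names(genes)) && length(genes))
        stop("gene models must be named")
    anch <- if (anchor == "tss")
        GenomicRanges::resize(genes, width = 1L, fix = "start")
    else genes
    ## disjoint seqlevel sets (e.g. peaks confined to other chromosomes)
    ## are legitimate input, not worth a merge warning
    hits <- suppressWarnings(
        GenomicRanges::findOverlaps(anch, peaks, maxgap = windowBp,
                                    ignore.strand = TRUE))
    sort(unique(names(genes)[S4Vectors::queryHits(hits)]))
}

#' Gene-by-subunit binding matrix
#'
#' @param genes named GRanges of gene models.
#' @param peaksList named list of peak GRanges, one per subunit.
#' @inheritParams assignBinding
#' @return Logical matrix, genes x subunits, with attribute `window_bp`.
#' @export
bindingMatrix <- function(genes, peaksList, windowBp = 1000L,
                          anchor = c("gene", "tss")) {
    anchor <- match.arg(anchor)
    stopifnot(is.list(peaksList), !is.null(names(peaksList)))
    m <- vapply(peaksList, function(p)
        names(genes) %in% assignBinding(genes, p, windowBp, anchor),
        logical(length(genes)))
    m <- matrix(m, nrow = length(genes),
                dimnames = list(names(genes), names(peaksList)))
    attr(m, "window_bp") <- windowBp
    m
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact test conditioning on both margins. The reported odds ratio is the
#' unconditional sample estimate (a*d)/(b*c), with sentinels Inf (when
#' b*c = 0 < a*d), 0 (a*d = 0 < b*c) and 1 (both products zero). The
#' two-sided p-value sums the conditional hypergeometric pmf, computed in
#' log space, over all tables with the observed margins whose pmf does not
#' exceed the observed pmf by more than a factor 1 + 1e-7 (the standard
#' tie tolerance for exact 2x2 tests).
#'
#' @param a,b,c,d cell counts; rows are (DE, non-DE), columns (bound,
#'   unbound), so `a` = DE-and-bound. A 2x2 matrix may be given as `a`.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisherExact2x2(3, 1, 1, 3)  # OR = 9, p = 34/70
#' @export
fisherExact2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
    if (is.matrix(a)) {
        stopifnot(all(dim(a) == 2L))
        d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
    }
    cells <- c(a, b, c, d)
    if (any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers")
    if (sum(cells) == 0) stop("at least one margin must be positive")
    or <- if (b * c == 0 && a * d == 0) 1
          else if (b * c == 0) Inf
          else if (a * d == 0) 0
          else (a * d) / (b * c)
    N <- a + b + c + d
    m1 <- a + b        # row margin (DE)
    k1 <- a + c        # column margin (bound)
    lo <- max(0, m1 + k1 - N)
    hi <- min(m1, k1)
    support <- lo:hi
    lp <- lchoose(k1, support) + lchoose(N - k1, m1 - support) -
        lchoose(N, m1)
    lpObs <- lp[support == a]
    p <- min(1, sum(exp(lp[lp <= lpObs + log1p(1e-7)])))
    list(odds_ratio = or, p_value = p)
}

#' Binding enrichment of one subunit in one DE direction
#'
#' Builds the 2x2 table (DE vs non-DE) x (bound vs unbound) over the
#' background universe, runs [fisherExact2x2()], and reports the target
#' genes (DE-and-bound) and the target fraction.
#'
#' @param deSet gene IDs differentially expressed in this direction;
#'   members outside the background are dropped (and counted).
#' @param bound bound gene IDs (intersected with the background).
#' @param background gene universe (non-empty).
#' @param subunit,direction labels carried into the record.
#' @return A one-row [TargetEnrichmentResults-class].
#' @export
subunitEnrichment <- function(deSet, bound, background,
                              subunit = "TF", direction = "up") {
    background <- unique(as.character(background))
    if (!length(background)) stop("background is empty")
    nOut <- sum(!deSet %in% background)
    if (nOut)
        message(sprintf("subunitEnrichment: dropped %d DE gene(s) not in background",
                        nOut))
    deSet <- intersect(unique(as.character(deSet)), background)
    bound <- intersect(unique(as.character(bound)), background)
    targets <- defineTargets(deSet, bound)
    a <- length(targets)
    b <- length(deSet) - a
    cc <- length(bound) - a
    d <- length(background) - a - b - cc
    ft <- fisherExact2x2(a, b, cc, d)
    ## subunit-level sentinel: no DE gene bound means zero estimated
    ## enrichment, even when the c cell is also empty
    if (a == 0 && b > 0) ft$odds_ratio <- 0
    cm <- if (sum(a, b, cc, d) > 0)
        unname(stats::fisher.test(matrix(c(a, b, cc, d), 2L,
                                         byrow = TRUE))$estimate)
    else NA_real_
    res <- S4Vectors::DataFrame(
        subunit = subunit, direction = direction,
        a = a, b = b, c = cc, d = d,
        odds_ratio = ft$odds_ratio, or_cmle = cm,
        p_value = ft$p_value,
        fraction_pct = if (a + b > 0) targetFraction(a, a + b)
                       else NA_integer_,
        target_genes = S4Vectors::SimpleList(list(targets)))
    out <- methods::new("TargetEnrichmentResults", res)
    methods::validObject(out)
    out
}

#' Target genes: differentially expressed and bound
#'
#' @param deGenes,bound character vectors of gene IDs.
#' @return Sorted intersection.
#' @export
defineTargets <- function(deGenes, bound) {
    sort(intersect(unique(deGenes), unique(bound)))
}

#' Target fraction as an integer percentage
#'
#' 100 * nTargets / nDeDirection, rounded half-up to the nearest integer
#' percent (so 40 of 56 gives 71, 24 of 68 gives 35).
#'
#' @param nTargets number of target genes in one direction.
#' @param nDeDirection number of DE genes in that direction (> 0).
#' @return Integer percentage in \[0, 100\].
#' @export
targetFraction <- function(nTargets, nDeDirection) {
    if (nDeDirection <= 0) stop("nDeDirection must be > 0")
    if (nTargets < 0 || nTargets > nDeDirection)
        stop("need 0 <= nTargets <= nDeDirection")
    as.integer(floor(100 * nTargets / nDeDirection + 0.5))
}

#' Per-subunit, per-direction binding enrichment of DE genes
#'
#' The background is the set of genes in the DE table that have
#' coordinates in the gene-model table (genes without coordinates are
#' excluded and counted). For each subunit, binding is assigned by the
#' window rule; each direction's DE set is then tested with Fisher's
#' exact test.
#'
#' @param de a gene-level [DEResults-class] (or a list with elements `up`
#'   and `down` of gene IDs plus `universe`).
#' @param genes named GRanges of gene models.
#' @param peaksList named list of peak GRanges, one per subunit.
#' @inheritParams assignBinding
#' @return A [TargetEnrichmentResults-class] with one row per
#'   subunit x direction; `metadata()` records the window, anchor and the
#'   number of DE-table genes without coordinates.
#' @export
analyzeTargets <- function(de, genes, peaksList, windowBp = 1000L,
                           anchor = c("gene", "tss")) {
    anchor <- match.arg(anchor)
    stopifnot(is.list(peaksList), length(peaksList) >= 1L,
              !is.null(names(peaksList)))
    if (methods::is(de, "DEResults")) {
        universe <- rownames(de)
        sets <- list(up = deGenes(de, "up"), down = deGenes(de, "down"))
    } else {
        universe <- de$universe
        sets <- list(up = de$up, down = de$down)
    }
    background <- intersect(universe, names(genes))
    nNoCoord <- length(universe) - length(background)
    if (nNoCoord)
        message(sprintf("analyzeTargets: %d gene(s) without coordinates excluded from background",
                        nNoCoord))
    if (!length(background)) stop("empty background: no DE-table gene has coordinates")
    rows <- list()
    for (su in names(peaksList)) {
        bound <- assignBinding(genes, peaksList[[su]], windowBp, anchor)
        for (dir in c("up", "down"))
            rows[[paste(su, dir)]] <- subunitEnrichment(
                sets[[dir]], bound, background, subunit = su,
                direction = dir)
    }
    res <- do.call(rbind, unname(rows))
    out <- methods::new("TargetEnrichmentResults", res)
    S4Vectors::metadata(out) <- list(windowBp = windowBp, anchor = anchor,
                                     nNoCoord = nNoCoord,
                                     nBackground = length(background))
    methods::validObject(out)
    out
}
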