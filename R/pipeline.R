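#' Run the full target-identification pipeline
#'
#' Orchestrates normalization, differential expression, optional
#' over-representation analysis, and per-subunit binding enrichment, and
#' assembles a deterministic run manifest. Linear-scale input is quantile
#' normalized and then log2 transformed; log2 input is quantile normalized
#' unless `skipNormalize = TRUE`.
#'
#' @param expr an [ExpressionTable-class] (linear or log2 scale).
#' @param genes named [GenomicRanges::GRanges] of gene models.
#' @param peaksList named list of peak GRanges, one per subunit.
#' @param geneSets optional [GeneSetCollection-class] for ORA.
#' @param probeMap optional probe-to-gene data.frame (`probe_id`,
#'   `gene_id`); when given, BH runs at probe level and statistics are
#'   collapsed to genes before enrichment.
#' @param fdrThreshold DE and ORA FDR cutoff (default 0.05).
#' @param windowBp binding window in bp (default 1000).
#' @param minSetSize minimum tested gene-set size (default 2).
#' @param skipNormalize skip quantile normalization of log2 input.
#' @param anchor `"gene"` or `"tss"` (see [assignBinding()]).
#' @param outDir if non-NULL, all tables plus the manifest are written
#'   there via [writeResults()]; identical inputs give byte-identical
#'   files.
#' @param seed seed to record in the manifest (the pipeline itself is
#'   deterministic; randomness lives in the generator).
#' @return List with `de` (gene- or probe-level [DEResults-class]), `ora`
#'   (or NULL), `targets` ([TargetEnrichmentResults-class]) and `manifest`.
#' @export
runPipeline <- function(expr, genes, peaksList, geneSets = NULL,
                        probeMap = NULL, fdrThreshold = 0.05,
                        windowBp = 1000L, minSetSize = 2L,
                        skipNormalize = FALSE,
                        anchor = c("gene", "tss"), outDir = NULL,
                        seed = NULL) {
    anchor <- match.arg(anchor)
    stopifnot(methods::is(expr, "ExpressionTable"))
    nInput <- nrow(expr)
    if (identical(valueScale(expr), "linear")) {
        expr <- log2Transform(quantileNormalize(expr))
    } else if (!skipNormalize) {
        expr <- quantileNormalize(expr)
    }
    de <- runDE(expr, fdrThreshold = fdrThreshold)
    if (!is.null(probeMap))
        de <- collapseProbesToGenes(de, probeMap)
    up <- deGenes(de, "up"); down <- deGenes(de, "down")
    ora <- NULL
    if (!is.null(geneSets) && length(c(up, down))) {
        ora <- oraAnalyze(c(up, down), geneSets, rownames(de),
                          minSetSize = minSetSize,
                          fdrThreshold = fdrThreshold)
    }
    targets <- analyzeTargets(de, genes, peaksList, windowBp = windowBp,
                              anchor = anchor)
    md <- S4Vectors::metadata(targets)
    manifest <- list(
        parameters = list(fdrThreshold = fdrThreshold,
                          windowBp = windowBp, minSetSize = minSetSize,
                          anchor = anchor, skipNormalize = skipNormalize),
        seed = seed,
        counts = list(
            features_in = nInput,
            features_tested = nrow(de),
            probes_unmapped = S4Vectors::metadata(de)$nUnmapped %||% 0L,
            ambiguous_genes = length(S4Vectors::metadata(de)$ambiguousGenes),
            de_total = length(c(up, down)),
            de_up = length(up), de_down = length(down),
            background_with_coords = md$nBackground,
            genes_without_coords = md$nNoCoord),
        subunits = names(peaksList))
    if (!is.null(outDir)) {
        writeResults(list(de = de, ora = ora, targets = targets), outDir,
                     params = manifest$parameters, seed = seed)
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE,
                             digits = NA, null = "null")
    }
    list(de = de, ora = ora, targets = targets, manifest = manifest)
}

#' Fold-enrichment bar chart
#'
#' Simple horizontal bar chart of the top over-represented gene sets, in
#' the style of a standard ORA summary figure.
#'
#' @param x an [EnrichmentResults-class].
#' @param top number of sets to show (default 10).
#' @param ... passed to [graphics::barplot].
#' @return Invisibly, the plotted subset.
#' @export
plotFoldEnrichment <- function(x, top = 10L, ...) {
    stopifnot(methods::is(x, "EnrichmentResults"))
    sub <- utils::head(x, top)
    if (!nrow(sub)) {
        warning("nothing to plot")
        return(invisible(sub))
    }
    op <- graphics::par(mar = c(4, 12, 2, 1))
    on.exit(graphics::par(op))
    graphics::barplot(rev(sub$fold_enrichment),
                      names.arg = rev(sub$set_name), horiz = TRUE,
                      las = 1, xlab = "fold enrichment", ...)
    invisible(sub)
}
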