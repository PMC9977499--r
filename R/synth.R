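## Coupled synthetic expression / gene-model / ChIP-peak generator with
## known ground truth. Defaults emulate the motivating study design: two
## groups of 3 arrays, ~1% DE genes split evenly up/down with log2 effects
## of 0.8-2.0, and promoter binding whose odds are multiplied by 4 for the
## RelB subunit among upregulated genes (baseline binding probability
## 0.15). Every generator is a pure function of (config, seed); each stage
## draws from a child stream derived from the master seed by a fixed
## label, so adding a stage never perturbs earlier stages.

#' Simulation configuration
#'
#' @param n_genes number of genes (default 12000, array-scale universe).
#' @param n_per_group arrays per group (default 3).
#' @param pi_de fraction of DE genes (default 0.01), split evenly between
#'   up (higher in group A, the fetal analogue) and down.
#' @param effect_size_range log2 effect magnitudes, drawn uniformly
#'   (default \[0.8, 2.0\]).
#' @param mu0,sd_mu hyperparameters of the per-gene baseline mean, log2
#'   scale (defaults 7 and 2).
#' @param sd_noise_range per-gene noise SD range, log2 units
#'   (default \[0.15, 0.45\]).
#' @param p0_bound baseline promoter-binding probability per subunit
#'   (default 0.15).
#' @param or_true named multiplicative binding-odds factor for up-DE genes
#'   per subunit; default RelB = 4, others 1.
#' @param gene_length_range,intergap_range gene length and intergenic gap
#'   ranges in bp (defaults \[2000, 10000\] and \[5000, 50000\]).
#' @param n_bg_peaks intergenic decoy peaks per subunit (default 2000).
#' @param peak_length peak width in bp (default 300).
#' @param seed master integer seed.
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(n_genes = 12000L, n_per_group = 3L, pi_de = 0.01,
                      effect_size_range = c(0.8, 2.0), mu0 = 7, sd_mu = 2,
                      sd_noise_range = c(0.15, 0.45), p0_bound = 0.15,
                      or_true = c(p65 = 1, p50 = 1, RelB = 4, p52 = 1),
                      gene_length_range = c(2000L, 10000L),
                      intergap_range = c(5000L, 50000L),
                      n_bg_peaks = 2000L, peak_length = 300L, seed = 1L) {
    cfg <- list(n_genes = as.integer(n_genes),
                n_per_group = as.integer(n_per_group), pi_de = pi_de,
                effect_size_range = effect_size_range, mu0 = mu0,
                sd_mu = sd_mu, sd_noise_range = sd_noise_range,
                p0_bound = p0_bound, or_true = or_true,
                gene_length_range = gene_length_range,
                intergap_range = intergap_range,
                n_bg_peaks = as.integer(n_bg_peaks),
                peak_length = as.integer(peak_length),
                seed = as.integer(seed))
    if (cfg$n_genes < 0 || cfg$n_per_group < 1)
        stop("n_genes must be >= 0 and n_per_group >= 1")
    if (pi_de < 0 || pi_de > 1 || p0_bound < 0 || p0_bound > 1)
        stop("probabilities must lie in [0, 1]")
    if (any(or_true <= 0)) stop("or_true must be > 0")
    if (is.null(names(or_true)) || any(!nzchar(names(or_true))))
        stop("or_true must be a named vector (one entry per subunit)")
    for (rg in list(effect_size_range, sd_noise_range, gene_length_range,
                    intergap_range))
        if (length(rg) != 2L || rg[1L] > rg[2L] || any(rg < 0))
            stop("ranges must be ordered pairs of non-negative numbers")
    ## truth-bound promoter peaks may extend window + peak_length past a
    ## gene; gaps must keep them > window away from the neighbours
    if (cfg$intergap_range[1L] < 2 * (1000 + cfg$peak_length) + 2)
        stop("intergap_range minimum too small to separate promoter peaks from neighbouring genes")
    structure(cfg, class = "SimConfig")
}

## deterministic child seed from master seed + stage label (< 2^31)
.childSeed <- function(seed, label) {
    h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
    as.integer((abs(seed) %% 1048576L) * 1024L + (h %% 1024L)) %% 2147483629L
}

#' Simulate non-overlapping gene models on one synthetic chromosome
#'
#' Gene lengths and intergenic gaps are drawn uniformly from the
#' configured ranges; genes are coordinate-sorted and pairwise disjoint.
#'
#' @param config a [simConfig()].
#' @return Named [GenomicRanges::GRanges] (`gene00001`, ...), strand `+`.
#' @export
simulateGenome <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    n <- config$n_genes
    if (n == 0L) return(GenomicRanges::GRanges())
    withr::with_seed(.childSeed(config$seed, "genome"), {
        len <- round(stats::runif(n, config$gene_length_range[1L],
                                  config$gene_length_range[2L]))
        gap <- round(stats::runif(n, config$intergap_range[1L],
                                  config$intergap_range[2L]))
    })
    start0 <- cumsum(gap) + c(0, cumsum(len))[seq_len(n)]
    gr <- GenomicRanges::GRanges(
        "chrS", IRanges::IRanges(start = start0 + 1, width = len),
        strand = "+")
    names(gr) <- sprintf("gene%05d", seq_len(n))
    gr
}

#' Simulate a two-group expression experiment with known DE truth
#'
#' Log2-scale values: per-gene baseline ~ Normal(mu0, sd_mu), plus a
#' group-B shift of -delta (up genes) or +delta (down genes) with
#' delta ~ Uniform(effect_size_range), plus Normal(0, sd_g) noise with
#' sd_g ~ Uniform(sd_noise_range). floor(pi_de * n_genes) genes are DE,
#' split evenly up/down ("up" = higher in group A, the fetal analogue).
#'
#' @param config a [simConfig()].
#' @param genes gene models from [simulateGenome()] (non-empty).
#' @return List with `expr` (an [ExpressionTable-class], log2 scale) and
#'   `truth` (list with `de_up`, `de_down`, `delta` named by DE gene).
#' @export
simulateExpression <- function(config, genes) {
    stopifnot(inherits(config, "SimConfig"))
    if (!length(genes)) stop("genes must be non-empty")
    ids <- names(genes)
    n <- length(ids)
    m <- config$n_per_group
    nDE <- floor(config$pi_de * n)
    if (config$pi_de > 0 && nDE < 2L) {
        warning("pi_de * n_genes < 2: generating zero DE genes")
        nDE <- 0L
    }
    sids <- c(sprintf("fetal_%d", seq_len(m)),
              sprintf("adult_%d", seq_len(m)))
    groups <- stats::setNames(rep(c("fetal", "adult"), each = m), sids)
    withr::with_seed(.childSeed(config$seed, "expression"), {
        de <- if (nDE) sample(ids, nDE) else character()
        nUp <- ceiling(nDE / 2)
        deUp <- de[seq_len(nUp)]
        deDown <- de[setdiff(seq_len(nDE), seq_len(nUp))]
        baseline <- stats::rnorm(n, config$mu0, config$sd_mu)
        sdg <- stats::runif(n, config$sd_noise_range[1L],
                            config$sd_noise_range[2L])
        delta <- stats::runif(nDE, config$effect_size_range[1L],
                              config$effect_size_range[2L])
        noise <- matrix(stats::rnorm(n * 2 * m, 0, sdg), n, 2 * m)
    })
    shiftB <- numeric(n)
    names(delta) <- de
    shiftB[match(deUp, ids)] <- -delta[deUp]
    shiftB[match(deDown, ids)] <- delta[deDown]
    v <- baseline + noise
    v[, seq_len(m) + m] <- v[, seq_len(m) + m] + shiftB
    dimnames(v) <- list(ids, sids)
    list(expr = ExpressionTable(v, groups, scale = "log2"),
         truth = list(de_up = deUp, de_down = deDown, delta = delta))
}

#' Simulate per-subunit ChIP-Seq peak calls with known binding truth
#'
#' For each subunit, each gene is truth-bound with probability p1 where
#' odds(p1) = odds(p0_bound) * or_true for up-DE genes and odds(p0_bound)
#' otherwise. Each truth-bound gene receives one peak of `peak_length`
#' placed uniformly with a gap of at most 1000 bp to the gene (possibly
#' overlapping it); decoy peaks are placed in intergenic space at a gap
#' greater than 1000 bp from every gene, so the 1 kb binding rule recovers
#' the truth exactly.
#'
#' @param config a [simConfig()].
#' @param genes gene models from [simulateGenome()].
#' @param truth partial truth from [simulateExpression()].
#' @return List with `peaks` (named list of GRanges, one per subunit) and
#'   the completed `truth` (adds `bound` and `or_true`).
#' @export
simulatePeaks <- function(config, genes, truth) {
    stopifnot(inherits(config, "SimConfig"))
    ids <- names(genes)
    n <- length(ids)
    window <- 1000L                     # the 1 kb rule's window
    pk <- config$peak_length
    odds0 <- config$p0_bound / (1 - config$p0_bound)
    s0 <- GenomicRanges::start(genes) - 1L
    e0 <- GenomicRanges::end(genes)
    ## intergenic space where a decoy keeps gap > window from both sides
    gapLo <- c(0, e0) + window + 1L          # min allowed peak start0
    gapHi <- c(s0, Inf)[seq_len(n + 1L)] - window - pk - 1L
    gapHi[n + 1L] <- e0[n] + max(config$intergap_range)  # tail space
    okGap <- which(gapHi - gapLo >= 0)
    avail <- (gapHi - gapLo + 1)[okGap]
    if (config$n_bg_peaks > 0 && (!length(okGap) || sum(avail) <= 0))
        stop("insufficient intergenic space for decoy peaks; increase intergap_range")
    peaks <- list()
    bound <- list()
    for (su in names(config$or_true)) {
        withr::with_seed(.childSeed(config$seed, paste0("peaks_", su)), {
            p1odds <- odds0 * config$or_true[[su]]
            p <- rep(config$p0_bound, n)
            p[ids %in% truth$de_up] <- p1odds / (1 + p1odds)
            isBound <- stats::runif(n) < p
            bidx <- which(isBound)
            ## promoter peak start0 uniform in [s0-window-pk, e0+window]
            ps <- if (length(bidx))
                round(stats::runif(length(bidx),
                                   s0[bidx] - window - pk,
                                   e0[bidx] + window))
            else numeric()
            ## decoys: uniform over the allowed intergenic space
            dec <- if (config$n_bg_peaks > 0) {
                u <- stats::runif(config$n_bg_peaks, 0, sum(avail))
                csum <- c(0, cumsum(avail))
                slot <- findInterval(u, csum, rightmost.closed = TRUE)
                floor(gapLo[okGap][slot] + (u - csum[slot]))
            } else numeric()
        })
        start0 <- c(ps, dec)
        gr <- GenomicRanges::GRanges(
            "chrS", IRanges::IRanges(start = start0 + 1, width = pk))
        names(gr) <- sprintf("%s_peak_%05d", su, seq_along(gr))
        peaks[[su]] <- sort(gr)
        bound[[su]] <- ids[bidx]
    }
    truth$bound <- bound
    truth$or_true <- config$or_true
    list(peaks = peaks, truth = truth)
}

#' Simulate a complete coupled experiment
#'
#' Orchestrates [simulateGenome()], [simulateExpression()] and
#' [simulatePeaks()] from one master seed (deterministic child streams per
#' stage) and optionally writes all standard-format files: expression TSV,
#' groups TSV, genes BED, one peaks BED per subunit, truth JSON.
#'
#' @param config a [simConfig()].
#' @param outDir directory for on-disk output, or NULL (default) to keep
#'   everything in memory.
#' @param exponentiate write/return linear-scale intensities (2^x) instead
#'   of log2, to exercise the normalize-then-log pipeline entry.
#' @return List with `expr`, `genes`, `peaks`, `truth`, `config` and (if
#'   written) `files`.
#' @export
simulateExperiment <- function(config = simConfig(), outDir = NULL,
                               exponentiate = FALSE) {
    genes <- simulateGenome(config)
    ex <- simulateExpression(config, genes)
    pw <- simulatePeaks(config, genes, ex$truth)
    expr <- ex$expr
    if (exponentiate)
        expr <- ExpressionTable(2^exprValues(expr), sampleGroups(expr),
                                scale = "linear")
    out <- list(expr = expr, genes = genes, peaks = pw$peaks,
                truth = pw$truth, config = config)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        files <- c(
            expression = file.path(outDir, "expression.tsv"),
            groups = file.path(outDir, "groups.tsv"),
            genes = file.path(outDir, "genes.bed"))
        writeExpression(expr, files["expression"], files["groups"])
        writeBed(genes, files["genes"])
        for (su in names(pw$peaks)) {
            f <- file.path(outDir, sprintf("peaks_%s.bed", su))
            writeBed(pw$peaks[[su]], f)
            files[paste0("peaks_", su)] <- f
        }
        tf <- file.path(outDir, "truth.json")
        jsonlite::write_json(
            list(seed = config$seed, scale = valueScale(expr),
                 de_up = pw$truth$de_up, de_down = pw$truth$de_down,
                 bound = pw$truth$bound,
                 or_true = as.list(pw$truth$or_true)),
            tf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
        files["truth"] <- tf
        out$files <- files
    }
    out
}
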