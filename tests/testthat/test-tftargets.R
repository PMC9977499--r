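mkGenes <- function(starts0, ends0, chrom = "chr1") {
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start = starts0 + 1, end = ends0))
    names(gr) <- sprintf("g%02d", seq_along(gr))
    gr
}
mkPeaks <- function(starts0, ends0, chrom = "chr1") {
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(start = starts0 + 1,
                                            end = ends0))
}

test_that("the 1 kb binding rule handles overlap, gaps and the boundary", {
    gene <- mkGenes(5000, 8000)
    expect_identical(assignBinding(gene, mkPeaks(6000, 6100)), "g01")
    expect_identical(assignBinding(gene, mkPeaks(8900, 9000)), "g01")
    expect_identical(assignBinding(gene, mkPeaks(9100, 9200)),
                     character())
    # gap of exactly 1000 bp is bound (inclusive boundary), upstream too
    expect_identical(assignBinding(gene, mkPeaks(9000, 9050)), "g01")
    expect_identical(assignBinding(gene, mkPeaks(3950, 4000)), "g01")
    expect_identical(assignBinding(gene, mkPeaks(3950, 3999)),
                     character())
    # different chromosome never binds
    expect_identical(assignBinding(gene, mkPeaks(6000, 6100, "chr2")),
                     character())
})

test_that("sweep binding equals the all-pairs oracle and is monotone", {
    set.seed(71)
    for (i in 1:25) {
        genes <- randomIntervals(30, prefix = "g")
        peaks <- randomIntervals(40, prefix = "p")
        w <- sample(c(0L, 500L, 1000L, 2000L), 1)
        expect_identical(assignBinding(genes, peaks, w),
                         allPairsBinding(genes, peaks, w))
        expect_true(all(assignBinding(genes, peaks, w) %in%
                            assignBinding(genes, peaks, w + 500L)))
    }
})

test_that("TSS anchoring restricts binding to the start-site window", {
    gene <- mkGenes(5000, 8000)                  # TSS at 5000 (+)
    expect_identical(assignBinding(gene, mkPeaks(7000, 7100),
                                   anchor = "tss"), character())
    expect_identical(assignBinding(gene, mkPeaks(4100, 4200),
                                   anchor = "tss"), "g01")
    minus <- gene
    GenomicRanges::strand(minus) <- "-"          # TSS at 8000
    expect_identical(assignBinding(minus, mkPeaks(8500, 8600),
                                   anchor = "tss"), "g01")
    expect_identical(assignBinding(minus, mkPeaks(4500, 4600),
                                   anchor = "tss"), character())
})

test_that("Fisher exact 2x2 matches enumeration with correct sentinels", {
    bal <- fisherExact2x2(10, 10, 10, 10)
    expect_equal(bal$odds_ratio, 1)
    expect_equal(bal$p_value, 1)

    r <- fisherExact2x2(3, 1, 1, 3)
    expect_equal(r$odds_ratio, 9)
    expect_equal(r$p_value, 34 / 70, tolerance = 1e-12)

    rr <- fisherExact2x2(10, 0, 0, 10)
    expect_identical(rr$odds_ratio, Inf)
    expect_equal(rr$p_value, 2 / choose(20, 10), tolerance = 1e-12)

    expect_equal(fisherExact2x2(0, 5, 5, 5)$odds_ratio, 0)
    expect_equal(fisherExact2x2(0, 5, 0, 5)$odds_ratio, 1)
    expect_error(fisherExact2x2(-1, 2, 3, 4), "non-negative")
    expect_error(fisherExact2x2(0, 0, 0, 0), "margin")
    # matrix input, and invariance under row-and-column transposition
    expect_equal(fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
                 r)
    set.seed(81)
    for (i in 1:25) {
        tb <- as.vector(stats::rmultinom(1, sample(5:40, 1), rep(0.25, 4)))
        f1 <- fisherExact2x2(tb[1], tb[2], tb[3], tb[4])
        f2 <- fisherExact2x2(tb[4], tb[3], tb[2], tb[1])
        expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
        # independent route: stats::fisher.test two-sided p
        expect_equal(f1$p_value,
                     fisher.test(matrix(tb, 2))$p.value,
                     tolerance = 1e-9)
    }
})

test_that("subunit enrichment builds the 2x2 table over the background", {
    bg <- paste0("g", 1:10)
    rec <- subunitEnrichment(paste0("g", 1:4), c("g1", "g2", "g5"), bg,
                             subunit = "RelB", direction = "up")
    expect_equal(c(rec$a, rec$b, rec$c, rec$d), c(2, 2, 1, 5))
    expect_equal(rec$odds_ratio, 5)
    expect_equal(rec$p_value, 0.5, tolerance = 1e-12)
    expect_identical(rec$target_genes[[1]], c("g1", "g2"))
    expect_equal(rec$fraction_pct, 50L)
    expect_equal(rec$a + rec$b, 4)
    expect_equal(rec$a + rec$b + rec$c + rec$d, length(bg))

    # empty bound set: zero targets and the OR = 0 sentinel
    none <- subunitEnrichment(paste0("g", 1:4), character(), bg)
    expect_equal(none$a, 0)
    expect_equal(none$odds_ratio, 0)
    expect_length(none$target_genes[[1]], 0)
    expect_error(subunitEnrichment("g1", "g1", character()), "empty")
    expect_message(subunitEnrichment(c("g1", "zz"), "g1", bg), "dropped 1")
})

test_that("target definition and fractions follow the published convention", {
    expect_identical(defineTargets(c("g1", "g2", "g3"),
                                   c("g2", "g3", "g4")), c("g2", "g3"))
    expect_identical(defineTargets("a", "b"), character())
    expect_equal(targetFraction(40, 56), 71L)
    expect_equal(targetFraction(24, 68), 35L)
    expect_equal(targetFraction(0, 10), 0L)
    expect_equal(targetFraction(1, 200), 1L)   # 0.5 rounds half-up
    expect_error(targetFraction(1, 0), "> 0")
    expect_error(targetFraction(5, 4), "<=")
})

test_that("analyzeTargets tests every subunit in both directions", {
    set.seed(91)
    cfg <- simConfig(n_genes = 400, pi_de = 0.05, n_bg_peaks = 100,
                     seed = 17)
    sim <- simulateExperiment(cfg)
    fake <- list(up = sim$truth$de_up, down = sim$truth$de_down,
                 universe = names(sim$genes))
    res <- analyzeTargets(fake, sim$genes, sim$peaks)
    expect_equal(nrow(res), 8L)  # 4 subunits x 2 directions
    expect_setequal(unique(res$subunit), c("p65", "p50", "RelB", "p52"))
    up <- res[res$direction == "up", ]
    expect_true(all(up$a + up$b == length(sim$truth$de_up)))
    expect_true(all(res$a + res$b + res$c + res$d == length(sim$genes)))
    # target genes are exactly DE-direction intersect truth-bound
    relb <- res[res$subunit == "RelB" & res$direction == "up", ]
    expect_identical(relb$target_genes[[1]],
                     defineTargets(sim$truth$de_up,
                                   sim$truth$bound$RelB))
})
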