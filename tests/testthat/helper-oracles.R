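## Independent brute-force oracles, deliberately written with different
## machinery than the package (plain choose()/loops, no log-space tricks,
## no interval trees).

# hypergeometric pmf by direct binomial-coefficient arithmetic
brutePmf <- function(i, K, n, N) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
}

# upper tail P[X >= k] by summation
bruteHyperUpper <- function(k, K, n, N) {
    hi <- min(K, n)
    if (k > hi) return(0)
    sum(vapply(k:hi, brutePmf, 0, K = K, n = n, N = N))
}

# two-sided Fisher p for table [[a,b],[c,d]] by full enumeration over all
# tables with the observed margins
bruteFisherP <- function(a, b, c, d) {
    N <- a + b + c + d
    m1 <- a + b; k1 <- a + c
    lo <- max(0, m1 + k1 - N); hi <- min(m1, k1)
    pm <- vapply(lo:hi, brutePmf, 0, K = k1, n = m1, N = N)
    pobs <- pm[(lo:hi) == a]
    sum(pm[pm <= pobs * (1 + 1e-7)])
}

# BH step-up, written as the literal definition
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(m * ps[i:m] / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
}

# two-tailed t p-value via numerical integration of the t density
tCdfOracle <- function(t, df) {
    dens <- function(x) {
        gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
            (1 + x^2 / df)^(-(df + 1) / 2)
    }
    2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}

# quadratic all-pairs binding oracle on 0-based half-open coordinates,
# gap = max(gene_start - peak_end, peak_start - gene_end), inclusive bound
allPairsBinding <- function(genes, peaks, window) {
    gs <- GenomicRanges::start(genes) - 1L; ge <- GenomicRanges::end(genes)
    ps <- GenomicRanges::start(peaks) - 1L; pe <- GenomicRanges::end(peaks)
    gc <- as.character(GenomicRanges::seqnames(genes))
    pc <- as.character(GenomicRanges::seqnames(peaks))
    bound <- character()
    for (i in seq_along(genes)) {
        for (j in seq_along(peaks)) {
            if (gc[i] != pc[j]) next
            gap <- max(gs[i] - pe[j], ps[j] - ge[i])
            if (gap <= window) {
                bound <- c(bound, names(genes)[i])
                break
            }
        }
    }
    sort(unique(bound))
}

# random GRanges fixture on a couple of chromosomes
randomIntervals <- function(n, chroms = c("chr1", "chr2"), maxPos = 50000,
                            maxLen = 2000, prefix = "iv") {
    s0 <- sample.int(maxPos, n, replace = TRUE)
    w <- sample.int(maxLen, n, replace = TRUE)
    gr <- GenomicRanges::GRanges(
        sample(chroms, n, replace = TRUE),
        IRanges::IRanges(start = s0 + 1, width = w))
    names(gr) <- sprintf("%s%04d", prefix, seq_len(n))
    gr
}

# small two-group expression fixture
makeExpr <- function(values, nA = ncol(values) / 2) {
    sids <- colnames(values)
    g <- stats::setNames(rep(c("fetal", "adult"),
                             c(nA, ncol(values) - nA)), sids)
    ExpressionTable(values, g)
}
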