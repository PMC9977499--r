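test_that("quantile normalization matches the rank-mean algorithm", {
    m <- matrix(c(2, 6, 4, 8), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    out <- exprValues(quantileNormalize(makeExpr(m)))
    expect_equal(unname(out), matrix(c(3, 7, 3, 7), 2, 2))

    # identical columns are a fixed point
    m2 <- matrix(c(1, 2, 1, 2), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
    expect_equal(exprValues(quantileNormalize(makeExpr(m2))), m2)

    # ties get the average of the reference values of their tied ranks
    m3 <- matrix(c(1, 1, 2, 10, 20, 30), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    out3 <- exprValues(quantileNormalize(makeExpr(m3, nA = 1)))
    expect_equal(unname(out3[, 1]), c(8, 8, 16))     # ref = (5.5,10.5,16)
    expect_equal(unname(out3[, 2]), c(5.5, 10.5, 16))

    # three-way tie averages all three reference values
    m4 <- matrix(c(5, 5, 5, 10, 20, 30), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    out4 <- exprValues(quantileNormalize(makeExpr(m4, nA = 1)))
    expect_equal(unname(out4[, 1]), rep(mean(c(7.5, 12.5, 17.5)), 3))
})

test_that("quantile normalization is idempotent and equalizes columns", {
    set.seed(11)
    for (rep in 1:5) {
        m <- matrix(rexp(60 * 4, 1 / 100), 60, 4,
                    dimnames = list(sprintf("g%02d", 1:60),
                                    paste0("s", 1:4)))
        et <- makeExpr(m)
        q1 <- quantileNormalize(et)
        v1 <- exprValues(q1)
        sorted <- apply(v1, 2, sort)
        expect_equal(sorted, sorted[, c(2:4, 1)], ignore_attr = TRUE)
        expect_equal(unname(colMeans(v1)), rep(mean(v1), 4))
        expect_equal(exprValues(quantileNormalize(q1)), v1)
        # cross-check against limma on tie-free input
        expect_equal(unname(v1),
                     unname(limma::normalizeQuantiles(m)),
                     tolerance = 1e-12)
    }
    # single column unchanged
    m1 <- matrix(1:5 + 0.5, dimnames = list(paste0("g", 1:5), "s1"))
    et1 <- ExpressionTable(m1, c(s1 = "a"))
    expect_equal(exprValues(quantileNormalize(et1)), m1)
})

test_that("log2 transform converts linear intensities and flips the marker", {
    m <- matrix(c(8, 1, 2, 4), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    et <- ExpressionTable(m, c(s1 = "a", s2 = "b"), scale = "linear")
    lt <- log2Transform(et)
    expect_equal(unname(exprValues(lt)), matrix(c(3, 0, 1, 2), 2, 2))
    expect_identical(valueScale(lt), "log2")
    expect_error(log2Transform(lt), "linear")
    # a zero intensity is rejected with its location
    m[2, 1] <- 0
    expect_error(
        ExpressionTable(m, c(s1 = "a", s2 = "b"), scale = "linear"),
        "positive")
})

test_that("pooled t statistic matches the closed form and the t CDF", {
    r <- studentTTwoSample(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
    expect_equal(r$df, 4)
    expect_equal(r$p_value, 0.02131164, tolerance = 1e-6)

    same <- studentTTwoSample(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t_stat, 0)
    expect_equal(same$p_value, 1)

    degen <- studentTTwoSample(c(0, 0, 0), c(1, 1, 1))
    expect_equal(degen$t_stat, -Inf)
    expect_equal(degen$p_value, 0)
    expect_error(studentTTwoSample(1, c(1, 2)), "at least 2")

    # random grid against the closed-form pooled formula + integral CDF
    set.seed(21)
    for (i in 1:20) {
        na <- sample(2:6, 1); nb <- sample(2:6, 1)
        a <- rnorm(na); b <- rnorm(nb, 1)
        r <- studentTTwoSample(a, b)
        sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
        tref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
        expect_equal(r$t_stat, tref, tolerance = 1e-12)
        expect_equal(r$p_value, tCdfOracle(tref, na + nb - 2),
                     tolerance = 1e-9)
        # antisymmetry
        rs <- studentTTwoSample(b, a)
        expect_equal(rs$t_stat, -r$t_stat)
        expect_equal(rs$p_value, r$p_value)
    }
})

test_that("BH adjustment implements the step-up procedure", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(c(0.005, 0.049, 0.05)), c(0.015, 0.05, 0.05))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")

    set.seed(31)
    for (i in 1:50) {
        p <- runif(sample(1:40, 1))
        q <- bhAdjust(p)
        expect_equal(q, bhOracle(p), tolerance = 1e-14)
        expect_true(all(q >= p - 1e-15) && all(q <= 1))
        o <- order(p)
        expect_true(all(diff(q[o]) >= -1e-15))  # monotone in sorted order
    }
})

test_that("runDE calls DE by strict q < threshold with direction from diff", {
    set.seed(41)
    n <- 50
    m <- matrix(rnorm(n * 6, 7, 0.3), n, 6,
                dimnames = list(sprintf("g%02d", 1:n), paste0("s", 1:6)))
    m[1, 1:3] <- m[1, 1:3] + 5   # strong up (higher in group A)
    m[2, 4:6] <- m[2, 4:6] + 5   # strong down
    de <- runDE(makeExpr(m))
    expect_true(all(de$q_value >= de$p_value - 1e-15))
    expect_identical(de$direction, ifelse(de$diff > 0, "up", "down"))
    expect_identical(de$is_de, de$q_value < 0.05)
    expect_true("g01" %in% deGenes(de, "up"))
    expect_true("g02" %in% deGenes(de, "down"))

    # a gene whose q equals the threshold exactly is NOT called DE
    thr <- sort(de$q_value)[3]
    de2 <- runDE(makeExpr(m), fdrThreshold = thr)
    expect_false(any(de2$q_value == thr & de2$is_de))
    expect_true(all(de2$q_value[de2$is_de] < thr))

    expect_error(runDE(makeExpr(m[, 1:3], nA = 1)), "2 samples")
    lin <- ExpressionTable(2^m, sampleGroups(makeExpr(m)),
                           scale = "linear")
    expect_error(runDE(lin), "log2")
})

test_that("probe collapsing picks the min-q representative and flags conflicts", {
    p <- c(0.0001, 0.2, 0.0002, 0.0004, 0.5, 0.6)
    q <- bhAdjust(p)
    res <- S4Vectors::DataFrame(
        mean_A = c(8, 7, 8, 6, 7, 7), mean_B = c(7, 7.1, 7, 7, 7.2, 6.9),
        diff = c(1, -0.1, 1, -1, -0.2, 0.1),
        t_stat = c(9, -1, 8.5, -8, -0.5, 0.4), df = rep(4, 6),
        p_value = p, q_value = q,
        direction = c("up", "down", "up", "down", "down", "up"),
        is_de = q < 0.05, zero_variance = rep(FALSE, 6),
        row.names = paste0("probe", 1:6))
    de <- new("DEResults", res)
    S4Vectors::metadata(de) <- list(fdrThreshold = 0.05, level = "probe",
                                    groupA = "fetal", groupB = "adult",
                                    varEqual = TRUE)
    map <- data.frame(
        probe_id = c("probe1", "probe2", "probe3", "probe4", "probe5"),
        gene_id = c("geneA", "geneA", "geneB", "geneB", "geneC"))
    suppressMessages(g <- collapseProbesToGenes(de, map))

    # geneA: probes (q tiny, up) and (q = 0.3ish, down) -> inherits probe1
    expect_equal(g["geneA", "q_value"], q[1])
    expect_identical(g["geneA", "direction"], "up")
    expect_false(g["geneA", "ambiguous"])
    # geneB: two *significant* probes with opposite signs -> ambiguous
    expect_true(g["geneB", "ambiguous"])
    expect_false("geneB" %in% deGenes(g, "up"))
    expect_false("geneB" %in% deGenes(g, "down"))
    # probe6 unmapped and counted
    expect_equal(S4Vectors::metadata(g)$nUnmapped, 1L)
    expect_identical(S4Vectors::metadata(g)$level, "gene")
    expect_error(collapseProbesToGenes(de, map[0, ]), "empty")

    # one probe per gene is an identity up to renaming
    map1 <- data.frame(probe_id = paste0("probe", 1:6),
                       gene_id = paste0("gene", 1:6))
    g1 <- collapseProbesToGenes(de, map1)
    expect_equal(g1$p_value[order(g1$representative_probe)], p)
})

test_that("tie-breaking among probes uses smallest p then probe ID", {
    res <- S4Vectors::DataFrame(
        mean_A = c(8, 8, 8), mean_B = c(7, 7, 7), diff = c(1, 1, 1),
        t_stat = c(5, 5, 5), df = rep(4, 3),
        p_value = c(0.02, 0.01, 0.01), q_value = rep(0.03, 3),
        direction = rep("up", 3), is_de = rep(TRUE, 3),
        zero_variance = rep(FALSE, 3),
        row.names = c("pA", "pC", "pB"))
    de <- new("DEResults", res)
    S4Vectors::metadata(de) <- list(fdrThreshold = 0.05, level = "probe")
    map <- data.frame(probe_id = c("pA", "pB", "pC"), gene_id = "g")
    g <- collapseProbesToGenes(de, map)
    # equal q; smallest p is shared by pB and pC; lexicographic -> pB
    expect_identical(g$representative_probe, "pB")
})
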