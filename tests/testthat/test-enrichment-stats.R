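test_that("hypergeometric upper tail matches brute-force enumeration", {
    set.seed(11)
    for (i in 1:300) {
        N <- sample(2:60, 1)
        K <- sample(0:N, 1)
        n <- sample(0:N, 1)
        kmin <- max(0, n + K - N)
        k <- sample(kmin:min(n, K), 1)
        if (K == 0 || n == 0) next
        res <- hypergeomOverlapTest(N, K, n, k)
        expect_equal(res$p, oracleHyperTail(k, N, K, n), tolerance = 1e-10)
        pm <- oracleHyperPmf(N, K, n)
        expect_equal(sum(pm$prob), 1, tolerance = 1e-12)
    }
})

test_that("hypergeometric tail handles boundaries, tiny p and errors", {
    # sample must be all successes -> p = 1
    expect_equal(hypergeomOverlapTest(10, 10, 5, 5)$p, 1)
    # enumerated tail example
    expect_equal(hypergeomOverlapTest(40, 10, 8, 2)$p,
                 oracleHyperTail(2, 40, 10, 8), tolerance = 1e-12)
    # extreme tails stay representable well below double underflow of the
    # naive product form
    res <- hypergeomOverlapTest(63677, 25421, 836, 647)
    expect_gt(res$p, 0)
    expect_lt(res$p, 1e-100)
    # expected and O/E
    r <- hypergeomOverlapTest(26178, 9430, 100, 91)
    expect_equal(r$expected, 100 * 9430 / 26178)
    expect_equal(r$oeRatio, 91 / r$expected)
    expect_error(hypergeomOverlapTest(10, 0, 5, 1), "impossible")
    expect_error(hypergeomOverlapTest(10, 5, 4, 5), "min\\(n, K\\)")
    expect_error(hypergeomOverlapTest(10, 12, 5, 2), "exceed")
    # K = 0 with k = 0: p = 1, O/E undefined
    r0 <- hypergeomOverlapTest(10, 0, 5, 0)
    expect_equal(r0$p, 1)
    expect_true(is.na(r0$oeRatio))
})

test_that("tail probability is non-increasing in the overlap count", {
    for (N in c(20, 45)) {
        K <- floor(N / 3); n <- floor(N / 2)
        p <- vapply(0:min(n, K), function(k)
            hypergeomOverlapTest(N, K, n, k)$p, 1)
        expect_true(all(diff(p) <= 1e-12))
    }
})

test_that("two-tailed Fisher matches enumeration and the reference test", {
    expect_equal(fisherExactTwoTailed(matrix(c(3, 1, 1, 3), 2)), 34 / 70)
    expect_equal(fisherExactTwoTailed(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
    expect_equal(fisherExactTwoTailed(matrix(c(2, 2, 2, 2), 2)), 1)
    set.seed(21)
    for (i in 1:60) {
        tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
        if (sum(tab) == 0) next
        r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); tot <- sum(tab)
        degenerate <- r1 %in% c(0, tot) || c1 %in% c(0, tot)
        if (degenerate) {
            expect_warning(p <- fisherExactTwoTailed(tab), "degenerate")
            expect_equal(p, 1)
            next
        }
        p <- fisherExactTwoTailed(tab)
        expect_equal(p, oracleFisherTwoTailed(tab), tolerance = 1e-12)
        expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
        # two-tailed >= the smaller one-tailed p
        lo <- stats::fisher.test(tab, alternative = "less")$p.value
        hi <- stats::fisher.test(tab, alternative = "greater")$p.value
        expect_gte(p + 1e-12, min(lo, hi))
    }
})

test_that("chi-square test matches the hand computation and Fisher asymptotics", {
    r <- chiSquareTest(matrix(c(10, 10, 10, 10), 2))
    expect_equal(r$statistic, 0)
    expect_equal(r$p, 1)
    r <- chiSquareTest(matrix(c(20, 5, 5, 20), 2))
    expect_equal(r$statistic, 18)
    expect_equal(r$p, pchisq(18, 1, lower.tail = FALSE))
    # Yates correction shrinks the statistic
    ry <- chiSquareTest(matrix(c(20, 5, 5, 20), 2), correction = TRUE)
    expect_lt(ry$statistic, 18)
    expect_error(chiSquareTest(matrix(c(0, 0, 5, 5), 2)), "[Ff]isher")
    # large counts: agreement with Fisher within 10%
    big <- matrix(c(120, 80, 90, 110), 2)
    expect_equal(chiSquareTest(big)$p, fisherExactTwoTailed(big),
                 tolerance = 0.1)
})

test_that("combined score follows c = ln(p) * z with the analytic z", {
    expect_equal(combinedScore(1, 100, 20, 10, 8), 0)
    # k equal to the expected overlap gives z = 0 hence c = 0
    expect_equal(combinedScore(0.5, 100, 20, 10, 2), 0)
    v <- 10 * 0.2 * 0.8 * (90 / 99)
    expect_equal(combinedScore(0.01, 100, 20, 10, 8),
                 log(0.01) * (8 - 2) / sqrt(v))
    expect_error(combinedScore(0, 100, 20, 10, 8), "\\(0, 1\\]")
    # zero-variance configuration is undefined
    expect_true(is.na(combinedScore(0.5, 10, 10, 5, 5)))
})

test_that("p-value adjustment reproduces hand-worked step-up examples", {
    expect_equal(adjustPvalues(c(0.01, 0.02, 0.03), "bonferroni"),
                 c(0.03, 0.06, 0.09))
    expect_equal(adjustPvalues(c(0.01, 0.02, 0.03), "bh"),
                 c(0.03, 0.03, 0.03))
    expect_equal(adjustPvalues(0.2, "bh"), 0.2)
    expect_equal(adjustPvalues(0.2, "bonferroni"), 0.2)
    expect_error(adjustPvalues(c(0.1, 1.2), "bh"), "\\[0, 1\\]")
    set.seed(5)
    for (i in 1:20) {
        p <- runif(sample(2:40, 1))
        bh <- adjustPvalues(p, "bh")
        expect_true(all(bh >= p - 1e-12))           # never below nominal
        o <- order(p)
        expect_true(all(diff(bh[o]) >= -1e-12))     # monotone in sorted order
        expect_true(all(adjustPvalues(p, "bonferroni") >=
                            pmin(1, p * length(p)) - 1e-12))
    }
})

test_that("library-wide enrichment handles degenerate and planted cases", {
    bg <- sprintf("g%04d", 1:500)
    # the background itself as the only set: k = n, O/E = 1, p = 1
    lib <- GeneSetLibrary(list(all = bg))
    res <- geneSetEnrichment(bg[1:50], lib, bg)
    expect_equal(res$k, 50)
    expect_equal(res$oeRatio, 1)
    expect_equal(res$p, 1)
    # query disjoint from every set
    lib2 <- GeneSetLibrary(list(a = bg[1:30], b = bg[31:60]))
    res2 <- geneSetEnrichment(bg[400:450], lib2, bg)
    expect_true(all(res2$k == 0))
    expect_error(geneSetEnrichment(c(bg[1], "absent"), lib2, bg),
                 "absent from background")
    # planted enrichment ranks the planted sets first
    universe <- sprintf("u%05d", 1:2000)
    target <- universe[1:300]
    for (s in 1:3) {
        gen <- generateGeneSetLibrary(universe, nSets = 40,
                                      setSizeRange = c(80L, 120L),
                                      targetSet = target,
                                      enrichedSetCount = 4L,
                                      enrichmentOdds = 10, seed = s)
        res <- geneSetEnrichment(target, gen$library, universe)
        expect_setequal(res$set[1:4], gen$truth$enrichedSets)
        expect_true(all(diff(res$p) >= 0))   # sorted ascending
    }
})
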