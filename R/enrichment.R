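#' @importFrom stats dhyper pbinom pchisq p.adjust chisq.test median
NULL

## log of sum(exp(lx)) without leaving log space
.logSumExp <- function(lx) {
    m <- max(lx)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(lx - m)))
}

## log upper-tail P(X >= k) for X ~ Hypergeometric(N, K, n), summed in log
## space over the pmf so values down to ~1e-300 stay representable.
.logHyperUpperTail <- function(k, N, K, n) {
    kmax <- min(n, K)
    kmin <- max(0, n + K - N)
    if (k <= kmin) return(0)          # log(1)
    if (k > kmax) return(-Inf)
    .logSumExp(dhyper(k:kmax, K, N - K, n, log = TRUE))
}

.checkOverlapParams <- function(N, K, n, k) {
    stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L,
              length(k) == 1L)
    if (any(c(N, K, n, k) < 0) || any(c(N, K, n, k) != floor(c(N, K, n, k))))
        stop("N, K, n, k must be non-negative integers")
    if (K > N || n > N)
        stop("K and n must not exceed the population size N")
    if (k > min(n, K)) {
        if (K == 0 || n == 0)
            stop("k > 0 is impossible with K = 0 or n = 0")
        stop("k must not exceed min(n, K)")
    }
    invisible(TRUE)
}

#' Hypergeometric overlap enrichment test
#'
#' Tests whether an overlap of `k` genes between a query of size `n` and a
#' property class of size `K`, drawn from a population of `N` genes, is
#' larger than expected by chance.  Reports the expected overlap `n*K/N`,
#' the observed/expected (O/E) ratio, the upper-tail p-value
#' `P(X >= k)` computed by log-space summation of the hypergeometric pmf,
#' the point probability `P(X = k)` (column `pPrinted`; the convention
#' used by the published summary tables shipped with this package, see
#' `vignette("scars-methods")`), and the analytic combined score
#' ([combinedScore()]).
#'
#' @param N population size (e.g. annotated genes in the genome).
#' @param K number of population members with the property.
#' @param n query (sample) size.
#' @param k observed overlap.
#' @param setName optional label carried into the result.
#' @return A one-row [S4Vectors::DataFrame] with columns `set`, `N`, `K`,
#'   `n`, `k`, `expected`, `oeRatio`, `p`, `pPrinted`, `pAdjusted` (`NA`
#'   until adjusted across a family of tests) and `combinedScore`.
#' @examples
#' hypergeomOverlapTest(N = 26178, K = 9430, n = 100, k = 91)
#' @export
hypergeomOverlapTest <- function(N, K, n, k, setName = NA_character_) {
    .checkOverlapParams(N, K, n, k)
    expected <- n * K / N
    if (K == 0 || n == 0) {
        return(DataFrame(set = setName, N = N, K = K, n = n, k = k,
                         expected = expected, oeRatio = NA_real_,
                         p = 1, pPrinted = 1, pAdjusted = NA_real_,
                         combinedScore = NA_real_))
    }
    p <- exp(.logHyperUpperTail(k, N, K, n))
    pPoint <- dhyper(k, K, N - K, n)
    DataFrame(set = setName, N = N, K = K, n = n, k = k,
              expected = expected, oeRatio = k / expected,
              p = p, pPrinted = pPoint, pAdjusted = NA_real_,
              combinedScore = combinedScore(p, N, K, n, k))
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Enumerates all tables with the observed margins and sums the
#' probabilities of those whose point probability does not exceed the
#' observed one (with a `1 + 1e-7` relative tolerance for floating-point
#' ties), i.e. the standard two-sided exact test.
#'
#' @param table a 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisherExactTwoTailed(matrix(c(3, 1, 1, 3), 2))
#' @export
fisherExactTwoTailed <- function(table) {
    tab <- as.matrix(table)
    if (!all(dim(tab) == c(2L, 2L)))
        stop("table must be 2x2")
    if (any(tab < 0) || any(tab != floor(tab)))
        stop("counts must be non-negative integers")
    if (sum(tab) == 0)
        stop("at least one count must be positive")
    r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); tot <- sum(tab)
    if (r1 == 0 || r1 == tot || c1 == 0 || c1 == tot) {
        warning("degenerate margins; p = 1")
        return(1)
    }
    support <- max(0, r1 + c1 - tot):min(r1, c1)
    probs <- dhyper(support, c1, tot - c1, r1)
    pObs <- dhyper(tab[1L, 1L], c1, tot - c1, r1)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Pearson chi-square test for a 2x2 table
#'
#' @inheritParams fisherExactTwoTailed
#' @param correction apply the Yates continuity correction (default
#'   `FALSE`).
#' @return A list with `statistic` and `p` (1 df).
#' @examples
#' chiSquareTest(matrix(c(20, 5, 5, 20), 2))
#' @export
chiSquareTest <- function(table, correction = FALSE) {
    tab <- as.matrix(table)
    if (!all(dim(tab) == c(2L, 2L)))
        stop("table must be 2x2")
    if (any(tab < 0))
        stop("counts must be non-negative")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0))
        stop("zero expected cell count; use fisherExactTwoTailed() instead")
    ct <- suppressWarnings(chisq.test(tab, correct = correction))
    list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Analytic combined score for overlap enrichment
#'
#' Pairs significance with enrichment magnitude: `c = ln(p) * z`, where `z`
#' is the z-score of the observed overlap under the hypergeometric null,
#' `z = (k - nK/N) / sd` with variance `n (K/N)(1 - K/N)(N - n)/(N - 1)`.
#' Reported alongside the p-value, never in place of it.  A zero-variance
#' configuration yields `NA`.
#'
#' @param p the enrichment p-value (in `(0, 1]`).
#' @inheritParams hypergeomOverlapTest
#' @return The combined score (natural log).
#' @examples
#' combinedScore(1e-10, N = 100, K = 20, n = 10, k = 8)
#' @export
combinedScore <- function(p, N, K, n, k) {
    if (is.na(p) || p <= 0 || p > 1)
        stop("p must be in (0, 1]")
    v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
    if (v <= 0) return(NA_real_)
    z <- (k - n * K / N) / sqrt(v)
    log(p) * z
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up with enforced
#' monotonicity; input order is preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03), "bh")
#' @export
adjustPvalues <- function(p, method = c("bh", "bonferroni")) {
    method <- match.arg(method)
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni")[method])
}

#' Overlap enrichment of a query against a gene-set library
#'
#' Runs [hypergeomOverlapTest()] per library set with
#' `N = |background|`, `K = |set ∩ background|`, `n = |query|`,
#' `k = |query ∩ set|`, adjusts p-values across sets and sorts by p
#' ascending with a deterministic set-name tie-break.
#'
#' @param query character vector of query genes (must be a subset of
#'   `background`).
#' @param library a [GeneSetLibrary].
#' @param background character vector defining the tested gene universe;
#'   set members outside it are ignored.
#' @param adjustMethod passed to [adjustPvalues()].
#' @return A [S4Vectors::DataFrame] with one row per set.
#' @export
geneSetEnrichment <- function(query, library, background,
                              adjustMethod = "bh") {
    query <- unique(as.character(query))
    background <- unique(as.character(background))
    if (length(query) == 0L || length(background) == 0L)
        stop("query and background must be non-empty")
    extra <- setdiff(query, background)
    if (length(extra))
        stop("query genes absent from background: ",
             paste(utils::head(extra, 5L), collapse = ", "))
    res <- do.call(rbind, lapply(names(library), function(nm) {
        members <- intersect(library[[nm]], background)
        hypergeomOverlapTest(N = length(background), K = length(members),
                             n = length(query),
                             k = length(intersect(query, members)),
                             setName = nm)
    }))
    res$pAdjusted <- adjustPvalues(res$p, adjustMethod)
    res[order(res$p, res$set), ]
}
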