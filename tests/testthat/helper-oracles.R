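## Independent oracles used to cross-check the package implementations.
## All of them work by direct enumeration / brute force and never call the
## code paths they verify.

## hypergeometric pmf over the full support, via binomial coefficients
oracleHyperPmf <- function(N, K, n) {
    support <- max(0, n + K - N):min(n, K)
    list(support = support,
         prob = choose(K, support) * choose(N - K, n - support) /
             choose(N, n))
}

## upper-tail P(X >= k) by summing the enumerated pmf
oracleHyperTail <- function(k, N, K, n) {
    pm <- oracleHyperPmf(N, K, n)
    sum(pm$prob[pm$support >= k])
}

## two-sided Fisher p by full enumeration over tables with fixed margins
oracleFisherTwoTailed <- function(tab) {
    r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); tot <- sum(tab)
    pm <- oracleHyperPmf(tot, c1, r1)
    pObs <- pm$prob[pm$support == tab[1L, 1L]]
    sum(pm$prob[pm$prob <= pObs * (1 + 1e-7)])
}

## quadratic all-pairs proximity scan on BED (0-based half-open) coordinates
oracleAssociations <- function(elements, genes, window) {
    es <- GenomicRanges::start(elements) - 1L
    ee <- GenomicRanges::end(elements)
    gs <- GenomicRanges::start(genes) - 1L
    ge <- GenomicRanges::end(genes)
    echr <- as.character(GenomicRanges::seqnames(elements))
    gchr <- as.character(GenomicRanges::seqnames(genes))
    eid <- names(elements); gid <- names(genes)
    out <- list()
    for (i in seq_along(elements)) {
        same <- which(gchr == echr[i])
        gap <- pmax(0, pmax(es[i], gs[same]) - pmin(ee[i], ge[same]))
        hit <- same[gap <= window]
        if (length(hit))
            out[[length(out) + 1L]] <- data.frame(
                element_id = eid[i], gene_id = gid[hit],
                gap = gap[gap <= window])
    }
    if (!length(out))
        return(data.frame(element_id = character(0),
                          gene_id = character(0), gap = numeric(0)))
    res <- do.call(rbind, out)
    res[order(res$element_id, res$gene_id), , drop = FALSE]
}

## sensitivity/precision of MLME recovery on one generated cohort
recoveryStats <- function(cfg) {
    se <- generateExpressionMatrix(cfg)
    cc <- classifyMLME(expressionCalls(se),
                       S4Vectors::metadata(se)$panels, cfg$criteria)
    truth <- SummarizedExperiment::colData(se)$role == "MLME"
    c(sensitivity = sum(cc$isMlme & truth) / sum(truth),
      precision = if (sum(cc$isMlme)) sum(cc$isMlme & truth) /
          sum(cc$isMlme) else NA_real_)
}

## small call matrix with explicit per-cell marker counts, for boundary
## tests of the classification rule
callMatrixFor <- function(panels, epiN, teN, peN, trio = TRUE,
                          tert = TRUE) {
    genes <- panelGenes(panels)
    calls <- matrix(FALSE, length(genes), length(epiN),
                    dimnames = list(genes,
                                    paste0("c", seq_along(epiN))))
    for (j in seq_along(epiN)) {
        calls[panels@epi[seq_len(epiN[j])], j] <- TRUE
        calls[panels@te[seq_len(teN[j])], j] <- TRUE
        calls[panels@pe[seq_len(peN[j])], j] <- TRUE
        if (trio[min(j, length(trio))])
            calls[panels@trio, j] <- TRUE
        if (tert[min(j, length(tert))])
            calls[panels@telomeraseGene, j] <- TRUE
    }
    calls
}

tinyPanels <- function() {
    MarkerPanelSet(epi = sprintf("E%02d", 1:10),
                   te = sprintf("T%02d", 1:10),
                   pe = sprintf("P%02d", 1:6))
}
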