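#' @importFrom stats wilcox.test
NULL

#' Binary expression calls by population-median exceedance
#'
#' A gene is called expressed in a cell when its value strictly exceeds the
#' median of that gene across all cells (even cell counts use the standard
#' midpoint median).  Ties at the median are not-expressed, so a gene with
#' identical values in every cell yields all-`FALSE` calls.
#'
#' @param x a `SummarizedExperiment` (first assay used) or a numeric
#'   genes-by-cells matrix with dimnames; at least 2 cells.
#' @return A logical genes-by-cells matrix.
#' @examples
#' m <- matrix(c(1, 2, 3), 1, 3,
#'             dimnames = list("g", paste0("c", 1:3)))
#' expressionCalls(m)   # FALSE FALSE TRUE
#' @export
expressionCalls <- function(x) {
    m <- .exprMatrix(x)
    if (ncol(m) < 2L)
        stop("expression calls need at least 2 cells")
    med <- apply(m, 1L, median)
    m > med
}

#' Classify cells as MLME by lineage marker thresholds
#'
#' Applies the multi-lineage markers expressing (MLME) rule to a call
#' matrix: a cell is MLME when its called-expressed marker counts reach
#' the per-lineage minima of `criteria` (defaults 6 epiblast, 7
#' trophectoderm, 4 primitive endoderm), all three pluripotency trio genes
#' are called, and the telomerase gene is called.  Telomerase positivity
#' uses the same median-exceedance call as every other gene.
#'
#' @param calls logical genes-by-cells matrix from [expressionCalls()].
#' @param panels a [MarkerPanelSet].
#' @param criteria an [MLMECriteria].
#' @return A [S4Vectors::DataFrame] with one row per cell: `cellId`,
#'   `epiCount`, `teCount`, `peCount`, `trioOk`, `telomeraseOk`, `isMlme`.
#' @export
classifyMLME <- function(calls, panels, criteria = MLMECriteria()) {
    stopifnot(is.logical(calls), methods::is(panels, "MarkerPanelSet"),
              methods::is(criteria, "MLMECriteria"))
    missing <- setdiff(panelGenes(panels), rownames(calls))
    if (length(missing))
        stop("panel gene(s) absent from the call matrix: ",
             paste(missing, collapse = ", "))
    if (criteria@minEpi > length(panels@epi) ||
        criteria@minTe > length(panels@te) ||
        criteria@minPe > length(panels@pe))
        stop("criteria minima exceed the corresponding panel sizes")
    cnt <- function(genes) colSums(calls[genes, , drop = FALSE])
    epi <- cnt(panels@epi); te <- cnt(panels@te); pe <- cnt(panels@pe)
    trioOk <- cnt(panels@trio) == 3L
    telOk <- calls[panels@telomeraseGene, ]
    isMlme <- epi >= criteria@minEpi & te >= criteria@minTe &
        pe >= criteria@minPe
    if (criteria@requireTrio) isMlme <- isMlme & trioOk
    if (criteria@requireTelomerase) isMlme <- isMlme & telOk
    DataFrame(cellId = colnames(calls), epiCount = unname(epi),
              teCount = unname(te), peCount = unname(pe),
              trioOk = unname(trioOk), telomeraseOk = unname(telOk),
              isMlme = unname(isMlme))
}

#' Derive MLME up-/down-regulated gene sets
#'
#' Per-gene two-sample rank-sum (Wilcoxon) comparison of MLME versus
#' non-MLME cells with Benjamini-Hochberg adjustment; direction is the
#' sign of the difference of group medians.  The published tables report
#' such derived sets without stating their derivation method; this
#' rank-sum/BH/median-direction recipe is this package's own documented
#' choice (see `vignette("scars-methods")`).
#'
#' @inheritParams expressionCalls
#' @param mlme logical vector flagging the MLME cells (both groups need at
#'   least 2 cells).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param adjustMethod passed to [adjustPvalues()].
#' @return A list with character vectors `up` and `down` and the per-gene
#'   `table` (`DataFrame`: gene, p, pAdjusted, direction).
#' @export
deriveDegSets <- function(x, mlme, alpha = 0.05, adjustMethod = "bh") {
    m <- .exprMatrix(x)
    mlme <- as.logical(mlme)
    stopifnot(length(mlme) == ncol(m))
    if (sum(mlme) < 2L || sum(!mlme) < 2L)
        stop("both groups need at least 2 cells")
    g1 <- m[, mlme, drop = FALSE]
    g2 <- m[, !mlme, drop = FALSE]
    p <- vapply(seq_len(nrow(m)), function(i) {
        a <- g1[i, ]; b <- g2[i, ]
        if (length(unique(c(a, b))) == 1L) return(1)
        pv <- suppressWarnings(
            wilcox.test(a, b, exact = FALSE)$p.value)
        if (is.na(pv)) 1 else pv
    }, 1)
    direction <- apply(g1, 1L, median) - apply(g2, 1L, median)
    padj <- adjustPvalues(p, adjustMethod)
    sig <- padj < alpha
    list(up = rownames(m)[sig & direction > 0],
         down = rownames(m)[sig & direction < 0],
         table = DataFrame(gene = rownames(m), p = p, pAdjusted = padj,
                           direction = unname(direction)))
}
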