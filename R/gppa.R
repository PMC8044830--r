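#' @importFrom GenomicRanges findOverlaps distance resize reduce countOverlaps
#'   trim seqinfo
#' @importFrom S4Vectors queryHits subjectHits
NULL

.grIds <- function(gr, what) {
    id <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else names(gr)
    if (is.null(id))
        stop(what, " must carry ids in mcols()$name or names()")
    as.character(id)
}

#' Associate genes to regulatory elements by genomic proximity
#'
#' Genome-wide proximity placement analysis (GPPA) association rule: a
#' gene is associated with an element when both lie on the same chromosome
#' and the gap between their nearest interval boundaries is at most
#' `window` bp (overlapping intervals have gap 0; the boundary-gap
#' reading of "within +/-10 kb" is fixed and documented).  Strand is
#' ignored throughout.
#'
#' @param elements,genes `GRanges` with ids in `mcols()$name` or names.
#' @param window association window in bp (default 10000).
#' @param anchor `"body"` associates against the whole gene interval;
#'   `"tss"` against a strand-aware single-bp transcription start site
#'   (unstranded genes anchor at their left end).
#' @return A [ProximityMap].
#' @examples
#' e <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 101000))
#' names(e) <- "e1"
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(105001, 106000))
#' names(g) <- "g1"
#' associateGenes(e, g)   # gap 4000 -> associated
#' @export
associateGenes <- function(elements, genes, window = 10000,
                           anchor = c("body", "tss")) {
    anchor <- match.arg(anchor)
    eid <- .grIds(elements, "elements")
    gid <- .grIds(genes, "genes")
    ganchor <- if (anchor == "tss")
        resize(genes, width = 1L, fix = "start", ignore.strand = FALSE)
    else genes
    ## suppressed warning: disjoint seqlevel sets are a legitimate query
    ## (chromosome isolation) and simply produce no hits
    hits <- suppressWarnings(
        findOverlaps(ganchor, elements, maxgap = window,
                     ignore.strand = TRUE))
    gap <- distance(ganchor[queryHits(hits)], elements[subjectHits(hits)],
                    ignore.strand = TRUE)
    df <- DataFrame(element_id = eid[subjectHits(hits)],
                    gene_id = gid[queryHits(hits)], gap = as.numeric(gap))
    df <- df[!duplicated(paste(df$element_id, df$gene_id)), ]
    df <- df[order(df$element_id, df$gene_id), ]
    new("ProximityMap", hits = df, window = as.numeric(window),
        anchor = anchor, nElements = length(elements),
        nGenes = length(genes))
}

#' Genes of a proximity-defined regulatory network
#'
#' The de-duplicated union of all genes associated with any element in one
#' or more [ProximityMap]s; passing several maps yields the combined
#' network (e.g. naive-plus-primed enhancer networks).
#'
#' @param ... one or more `ProximityMap` objects.
#' @return Sorted character vector of unique gene ids.
#' @export
networkGenes <- function(...) {
    maps <- list(...)
    stopifnot(length(maps) > 0L,
              all(vapply(maps, methods::is, TRUE, "ProximityMap")))
    sort(unique(unlist(lapply(maps, function(m) m@hits$gene_id))))
}

#' Enrichment of an expression signature within a regulatory network
#'
#' Hypergeometric overlap test of a gene expression signature against the
#' gene set of an enhancer-proximity network:
#' `N = genomeGeneCount`, `K = |network|`, `n = |signature|`,
#' `k = |signature intersect network|`.  The default background of 63,677
#' genes dominates these p-values and is an explicit parameter.
#'
#' @param signature character vector of signature genes.
#' @param network character vector of network genes (see [networkGenes()]).
#' @param genomeGeneCount background gene count (default 63677).
#' @param setName optional label for the result row.
#' @return A one-row [S4Vectors::DataFrame], see [hypergeomOverlapTest()].
#' @export
signatureNetworkEnrichment <- function(signature, network,
                                       genomeGeneCount = 63677,
                                       setName = NA_character_) {
    signature <- unique(as.character(signature))
    network <- unique(as.character(network))
    if (genomeGeneCount < length(network) ||
        genomeGeneCount < length(signature))
        stop("genomeGeneCount must be at least as large as both gene sets")
    hypergeomOverlapTest(N = genomeGeneCount, K = length(network),
                         n = length(signature),
                         k = length(intersect(signature, network)),
                         setName = setName)
}

## count how many A intervals overlap any (extended, clipped) B interval,
## chromosome-aware, on plain IRanges for speed in permutation loops
.overlapCount <- function(aByChr, bStart, bEnd, bChr, window,
                          genomeLength) {
    s <- pmax(1, bStart - window)
    e <- pmin(genomeLength, bEnd + window)
    total <- 0L
    for (ch in names(aByChr)) {
        sel <- bChr == ch
        if (!any(sel)) next
        total <- total + sum(IRanges::countOverlaps(
            aByChr[[ch]], IRanges(s[sel], e[sel])) > 0)
    }
    total
}

#' Placement (co-localization) enrichment of two interval sets
#'
#' Tests whether elements of `featureA` overlap `featureB` (optionally
#' extended by `window` bp) more often than expected, taking the size in
#' bp of the covered regions into account.  In `"analytic"` mode the
#' expected count is `|A| * cov(B)/genomeLength` with a binomial
#' upper-tail p-value; in `"permutation"` mode `featureB` is shuffled
#' uniformly (lengths preserved, single sequence, no exclusion zones) and
#' the empirical p-value is `(1 + #{count >= observed}) / (1 + nShuffles)`.
#'
#' @param featureA,featureB `GRanges` on a shared coordinate system.
#' @param genomeLength total genome length in bp.
#' @param mode `"analytic"` or `"permutation"`.
#' @param window extension of `featureB` in bp before overlap counting.
#' @param nShuffles number of shuffles in permutation mode.
#' @param seed optional seed for permutation mode.
#' @return A list with `observed`, `expected`, `fold`, `p` and `mode`.
#' @export
placementEnrichment <- function(featureA, featureB, genomeLength,
                                mode = c("analytic", "permutation"),
                                window = 0, nShuffles = 1000, seed = NULL) {
    mode <- match.arg(mode)
    if (any(end(featureA) > genomeLength) ||
        any(end(featureB) > genomeLength))
        stop("features must fit within genomeLength")
    aByChr <- split(IRanges(start(featureA), end(featureA)),
                    as.character(seqnames(featureA)))
    bChr <- as.character(seqnames(featureB))
    observed <- .overlapCount(aByChr, start(featureB), end(featureB),
                              bChr, window, genomeLength)
    if (mode == "analytic") {
        ext <- GRanges(bChr,
                       IRanges(pmax(1, start(featureB) - window),
                               pmin(genomeLength, end(featureB) + window)))
        cov <- sum(width(reduce(ext, ignore.strand = TRUE)))
        pcov <- min(1, cov / genomeLength)
        expected <- length(featureA) * pcov
        p <- pbinom(observed - 1, length(featureA), pcov,
                    lower.tail = FALSE)
    } else {
        if (nShuffles < 1L) stop("nShuffles must be >= 1")
        if (!is.null(seed)) set.seed(as.integer(seed))
        w <- width(featureB)
        cnt <- vapply(seq_len(nShuffles), function(i) {
            s <- floor(runif(length(w), 0, genomeLength - w + 1)) + 1
            .overlapCount(aByChr, s, s + w - 1, bChr, window,
                          genomeLength)
        }, 1L)
        expected <- mean(cnt)
        p <- (1 + sum(cnt >= observed)) / (1 + nShuffles)
    }
    fold <- if (expected > 0) observed / expected else NA_real_
    list(observed = observed, expected = expected, fold = fold, p = p,
         mode = mode)
}
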