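grWith <- function(chrom, start0, end0, ids) {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start0 + 1, end0))
    names(gr) <- ids
    GenomicRanges::mcols(gr)$name <- ids
    gr
}

test_that("the +/-10 kb association rule uses boundary gaps", {
    e <- grWith("chr1", 100000, 101000, "e1")
    near <- grWith("chr1", 105000, 106000, "g1")     # gap 4000
    far <- grWith("chr1", 120000, 121000, "g2")      # gap 19000
    edge <- grWith("chr1", 111000, 112000, "g3")     # gap exactly 10000
    over <- grWith("chr1", 100500, 102000, "g4")     # overlapping: gap 0
    genes <- c(near, far, edge, over)
    pm <- associateGenes(e, genes)
    h <- proximityHits(pm)
    expect_setequal(h$gene_id, c("g1", "g3", "g4"))
    expect_equal(h$gap[h$gene_id == "g1"], 4000)
    expect_equal(h$gap[h$gene_id == "g3"], 10000)    # inclusive window
    expect_equal(h$gap[h$gene_id == "g4"], 0)
    # other chromosome never associates
    pm2 <- associateGenes(e, grWith("chr2", 100000, 101000, "gx"))
    expect_equal(nrow(proximityHits(pm2)), 0)
    # empty inputs give an empty map
    expect_equal(nrow(proximityHits(
        associateGenes(e[0], genes))), 0)
})

test_that("association equals the quadratic all-pairs oracle", {
    set.seed(17)
    for (i in 1:4) {
        nC <- sample(1:2, 1)
        chroms <- sprintf("chr%d", seq_len(nC))
        nE <- 60; nG <- 150
        es <- sample(0:5e5, nE); gs <- sample(0:5e5, nG)
        e <- grWith(sample(chroms, nE, TRUE), es, es + 800,
                    sprintf("e%03d", 1:nE))
        g <- grWith(sample(chroms, nG, TRUE), gs, gs + 2000,
                    sprintf("g%03d", 1:nG))
        got <- as.data.frame(proximityHits(associateGenes(e, g,
                                                          window = 10000)))
        want <- oracleAssociations(e, g, 10000)
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want)
    }
})

test_that("planted proximity structure is recovered exactly", {
    fx <- generateGenomeFixture(nGenes = 1000, nElements = 200,
                                plantedFraction = 0.3, window = 10000,
                                seed = 3)
    pm <- associateGenes(fx$elements, fx$genes)
    got <- unique(proximityHits(pm)$gene_id)
    expect_length(got, 300)
    expect_setequal(got, fx$truth$associatedGenes)
    # oracle equivalence at the full fixture scale (1,200 intervals)
    want <- oracleAssociations(fx$elements, fx$genes, 10000)
    expect_setequal(paste(proximityHits(pm)$element_id,
                          proximityHits(pm)$gene_id),
                    paste(want$element_id, want$gene_id))
})

test_that("enlarging the window never removes an association", {
    fx <- generateGenomeFixture(nGenes = 300, nElements = 60,
                                plantedFraction = 0.4, seed = 13)
    small <- proximityHits(associateGenes(fx$elements, fx$genes,
                                          window = 5000))
    large <- proximityHits(associateGenes(fx$elements, fx$genes,
                                          window = 20000))
    expect_true(all(paste(small$element_id, small$gene_id) %in%
                        paste(large$element_id, large$gene_id)))
})

test_that("network genes are the de-duplicated union across maps", {
    e <- grWith("chr1", c(0, 5000), c(1000, 6000), c("e1", "e2"))
    g <- grWith("chr1", 2000, 3000, "g1")    # within 10 kb of both
    pm <- associateGenes(e, g)
    expect_equal(networkGenes(pm), "g1")
    fx <- generateGenomeFixture(nGenes = 200, nElements = 40,
                                plantedFraction = 0.5, seed = 19)
    pmA <- associateGenes(fx$elements[1:20], fx$genes)
    pmB <- associateGenes(fx$elements[21:40], fx$genes)
    expect_setequal(networkGenes(pmA, pmB),
                    union(proximityHits(pmA)$gene_id,
                          proximityHits(pmB)$gene_id))
})

test_that("signature-network enrichment delegates to the overlap test", {
    net <- sprintf("n%05d", 1:18766)
    sig <- c(net[1:762], sprintf("s%04d", 1:(1496 - 762)))
    res <- signatureNetworkEnrichment(sig, net)
    expect_equal(res$N, 63677)
    expect_equal(res$k, 762)
    expect_equal(round(res$oeRatio, 2), 1.73)
    # signature fully inside the network reaches the maximal O/E
    res2 <- signatureNetworkEnrichment(net[1:100], net,
                                       genomeGeneCount = 63677)
    expect_equal(res2$k, 100)
    expect_equal(res2$oeRatio, 63677 / 18766)
    expect_error(signatureNetworkEnrichment(sig, net,
                                            genomeGeneCount = 1000),
                 "at least as large")
})

test_that("placement enrichment honours coverage and permutation nulls", {
    L <- 1e6
    A <- grWith("chr1", seq(0, 9e5, 1e5), seq(0, 9e5, 1e5) + 500,
                sprintf("a%02d", 1:10))
    # B covering the whole genome: every A element overlaps, fold = 1
    B <- grWith("chr1", 0, L, "b1")
    res <- placementEnrichment(A, B, L, mode = "analytic")
    expect_equal(res$observed, 10)
    expect_equal(res$fold, 1)
    # disjoint fixed placements: observed 0, empirical p ~ 1
    Bfar <- grWith("chr1", seq(0, 9e5, 1e5) + 50000,
                   seq(0, 9e5, 1e5) + 50400, sprintf("b%02d", 1:10))
    resP <- placementEnrichment(A, Bfar, L, mode = "permutation",
                                nShuffles = 99, seed = 1)
    expect_equal(resP$observed, 0)
    expect_equal(resP$p, 1)
    expect_error(placementEnrichment(A, Bfar, L, mode = "permutation",
                                     nShuffles = 0), "nShuffles")
    # planted co-localization: both modes call enrichment
    Bnear <- grWith("chr1", seq(0, 9e5, 1e5) + 400,
                    seq(0, 9e5, 1e5) + 900, sprintf("b%02d", 1:10))
    an <- placementEnrichment(A, Bnear, L, mode = "analytic")
    pe <- placementEnrichment(A, Bnear, L, mode = "permutation",
                              nShuffles = 499, seed = 2)
    expect_equal(an$observed, 10)
    expect_lt(an$p, 1e-6)
    expect_lt(pe$p, 0.05)
    expect_gt(an$fold, 1)
    expect_gt(pe$fold, 1)
})
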