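test_that("expression calls use strict median exceedance", {
    m <- matrix(c(1, 2, 3,
                  5, 5, 5), 2, 3, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("c", 1:3)))
    calls <- expressionCalls(m)
    expect_equal(unname(calls["g1", ]), c(FALSE, FALSE, TRUE))
    expect_false(any(calls["g2", ]))        # ties at the median: not expressed
    # even cell count: midpoint median
    m2 <- matrix(c(1, 2, 3, 4), 1, 4,
                 dimnames = list("g", paste0("c", 1:4)))
    expect_equal(unname(expressionCalls(m2)[1, ]),
                 c(FALSE, FALSE, TRUE, TRUE))
    expect_error(expressionCalls(m2[, 1, drop = FALSE]), "at least 2")
})

test_that("MLME rule applies exact per-lineage thresholds and gates", {
    panels <- tinyPanels()
    crit <- MLMECriteria()    # 6 / 7 / 4, trio + telomerase required
    calls <- callMatrixFor(panels,
                           epiN = c(6, 6, 6, 6, 6),
                           teN  = c(7, 6, 7, 7, 7),
                           peN  = c(4, 4, 3, 4, 4),
                           trio = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                           tert = c(TRUE, TRUE, TRUE, TRUE, FALSE))
    cc <- classifyMLME(calls, panels, crit)
    expect_equal(cc$isMlme, c(TRUE, FALSE, FALSE, FALSE, FALSE))
    expect_equal(cc$epiCount, rep(6, 5))
    expect_equal(cc$teCount, c(7, 6, 7, 7, 7))
    expect_equal(cc$trioOk, c(TRUE, TRUE, TRUE, FALSE, TRUE))
    expect_equal(cc$telomeraseOk, c(TRUE, TRUE, TRUE, TRUE, FALSE))
    # relaxed gates
    cc2 <- classifyMLME(calls, panels,
                        MLMECriteria(requireTrio = FALSE,
                                     requireTelomerase = FALSE))
    expect_equal(cc2$isMlme, c(TRUE, FALSE, FALSE, TRUE, TRUE))
    # errors: absent panel gene, thresholds above panel size
    expect_error(classifyMLME(calls[-1, ], panels, crit), "E01")
    expect_error(classifyMLME(calls, panels, MLMECriteria(minPe = 7)),
                 "exceed")
})

test_that("adding an expressed marker never revokes an MLME call", {
    panels <- tinyPanels()
    genes <- panelGenes(panels)
    set.seed(31)
    for (i in 1:20) {
        calls <- matrix(runif(length(genes) * 8) < 0.5, length(genes), 8,
                        dimnames = list(genes, paste0("c", 1:8)))
        before <- classifyMLME(calls, panels)$isMlme
        off <- which(!calls)
        calls[sample(off, 1)] <- TRUE
        after <- classifyMLME(calls, panels)$isMlme
        expect_true(all(after >= before))
    }
})

test_that("classification is invariant under cell and gene reordering", {
    cfg <- simulationConfig(nCells = 60, nMlme = 8, nGenes = 320,
                            seed = 4)
    se <- generateExpressionMatrix(cfg)
    m <- SummarizedExperiment::assay(se)
    panels <- S4Vectors::metadata(se)$panels
    cc <- classifyMLME(expressionCalls(m), panels)
    perm <- sample(ncol(m))
    gperm <- sample(nrow(m))
    cc2 <- classifyMLME(expressionCalls(m[gperm, perm]), panels)
    expect_equal(cc2$cellId, cc$cellId[perm])
    expect_equal(cc2$isMlme, cc$isMlme[perm])
})

test_that("noiseless planted cohorts are recovered exactly", {
    cfg <- simulationConfig(nCells = 1000, nMlme = 135, nGenes = 500,
                            noiseSd = 0, dropoutRate = 0, leakageRate = 0,
                            markerEffect = 5, seed = 7)
    se <- generateExpressionMatrix(cfg)
    cc <- classifyMLME(expressionCalls(se), S4Vectors::metadata(se)$panels)
    truth <- SummarizedExperiment::colData(se)$role == "MLME"
    expect_equal(sum(cc$isMlme), 135)
    expect_equal(cc$isMlme, unname(truth))
})

test_that("differential sets capture planted markers and control the null", {
    cfg <- simulationConfig(nCells = 300, nMlme = 60, nGenes = 320,
                            markerEffect = 5, noiseSd = 0.5, seed = 9)
    se <- generateExpressionMatrix(cfg)
    truth <- SummarizedExperiment::colData(se)$role == "MLME"
    deg <- deriveDegSets(se, truth)
    panels <- S4Vectors::metadata(se)$panels
    # trio and telomerase are exclusive to MLME cells: always recovered
    expect_true(all(c(panels@trio, panels@telomeraseGene) %in% deg$up))
    # most lineage markers are recovered; markers transcribed in fewer
    # than half of the MLME cells have a zero median difference and are
    # excluded by the direction rule, so recovery is not complete
    markers <- c(panels@epi, panels@te, panels@pe)
    expect_gt(mean(markers %in% deg$up), 0.8)
    # BH admits at most a few spurious background discoveries
    expect_lte(length(deg$down), 5)
    # permuted labels: discovery count stays at the nominal level
    set.seed(10)
    degNull <- deriveDegSets(se, sample(truth))
    expect_lte(length(degNull$up) + length(degNull$down),
               0.05 * nrow(se))
    # identical groups yield empty sets
    m <- matrix(rep(c(1, 2, 3, 4), each = 4), 4, 4, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:4)))
    degId <- deriveDegSets(m, c(TRUE, TRUE, FALSE, FALSE))
    expect_length(degId$up, 0)
    expect_length(degId$down, 0)
    expect_error(deriveDegSets(m, c(TRUE, FALSE, FALSE, FALSE)),
                 "at least 2")
})
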