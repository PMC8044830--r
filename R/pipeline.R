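#' @importFrom utils packageVersion write.table read.delim
NULL

.provenanceHeader <- function(stage, params) {
    kv <- vapply(names(params), function(nm)
        sprintf("%s=%s", nm, paste(format(params[[nm]]), collapse = ",")),
        "")
    c(sprintf("# scarsTools %s | stage: %s", packageVersion("scarsTools"),
              stage),
      paste0("# ", kv))
}

.writeStageTsv <- function(df, path, stage, params) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader(stage, params), con)
    suppressWarnings(write.table(as.data.frame(df), con, sep = "\t",
                                 quote = FALSE, row.names = FALSE))
    invisible(path)
}

#' Run the simulate / classify / enrich pipeline
#'
#' Orchestrates the full synthetic workflow: generates an expression
#' matrix with planted MLME cells, classifies every cell, derives the
#' MLME up-/down-regulated gene sets, builds a gene-set library with the
#' up-set as planted target and runs the overlap enrichment stage.  Every
#' output file starts with `#`-prefixed provenance lines recording the
#' package version, the stage and the parameters that dominate the
#' results (seed, thresholds, background size, adjustment method).  The
#' result bundle is byte-identical across runs with the same config.
#'
#' @param config a [simulationConfig()].
#' @param outputDir directory for the result bundle (created if needed).
#' @param nSets,enrichedSetCount,enrichmentOdds library generation
#'   parameters (see [generateGeneSetLibrary()]).
#' @param alpha significance level of the differential-expression stage.
#' @param adjustMethod multiple-testing adjustment (`"bh"` or
#'   `"bonferroni"`).
#' @return Invisibly, a list with the in-memory stage results (`se`,
#'   `calls`, `cellCalls`, `degSets`, `enrichment`) and `files`.
#' @export
runPipeline <- function(config = simulationConfig(), outputDir,
                        nSets = 50L, enrichedSetCount = 5L,
                        enrichmentOdds = 10, alpha = 0.05,
                        adjustMethod = "bh") {
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
    se <- generateExpressionMatrix(config)
    writeExpressionTsv(se, file.path(outputDir, "expression.tsv"))
    calls <- expressionCalls(se)
    cellCalls <- classifyMLME(calls, metadata(se)$panels, config$criteria)
    .writeStageTsv(cellCalls, file.path(outputDir, "cell_calls.tsv"),
                   "classify",
                   list(seed = config$seed, minEpi = config$criteria@minEpi,
                        minTe = config$criteria@minTe,
                        minPe = config$criteria@minPe))
    deg <- deriveDegSets(se, cellCalls$isMlme, alpha = alpha,
                         adjustMethod = adjustMethod)
    writeLines(deg$up, file.path(outputDir, "mlme_up_genes.txt"))
    writeLines(deg$down, file.path(outputDir, "mlme_down_genes.txt"))
    background <- rownames(se)
    lib <- generateGeneSetLibrary(universe = background, nSets = nSets,
                                  setSizeRange = c(20L, 100L),
                                  targetSet = deg$up,
                                  enrichedSetCount = enrichedSetCount,
                                  enrichmentOdds = enrichmentOdds,
                                  seed = config$seed)
    writeGmt(lib$library, file.path(outputDir, "library.gmt"))
    enr <- if (length(deg$up))
        geneSetEnrichment(deg$up, lib$library, background,
                          adjustMethod = adjustMethod)
    else NULL
    if (!is.null(enr))
        .writeStageTsv(enr, file.path(outputDir, "enrichment.tsv"),
                       "enrich",
                       list(seed = config$seed,
                            background = length(background),
                            adjust = adjustMethod,
                            pTail = "upper-inclusive"))
    invisible(list(se = se, calls = calls, cellCalls = cellCalls,
                   degSets = deg, enrichment = enr,
                   files = list.files(outputDir, full.names = TRUE)))
}

.signifEq <- function(a, b, digits) {
    isTRUE(all.equal(signif(a, digits), signif(b, digits),
                     tolerance = 1e-8))
}

#' Replay the published count tables through the statistics layer
#'
#' For every row of the published count fixtures
#' ([referenceCountTables()] or TSVs written by
#' [writeReferenceCountFixtures()]), recomputes the observed/expected
#' ratio (2 decimal places), the overlap percentage (published precision)
#' and the hypergeometric p-value (4 significant figures,
#' point-probability convention, with the upper-tail p reported
#' alongside), and compares each with the published value.  The stemness
#' matrix node totals are checked against the column-sum formula; a
#' printed total that disagrees with its own column sum is flagged, not
#' asserted.
#'
#' @param fixtureDir optional directory of fixture TSVs; defaults to the
#'   tables compiled into the package.
#' @return A `data.frame` report with columns `table_id`, `row_label`,
#'   `metric`, `printed`, `recomputed`, `match`, with attribute
#'   `"ok"` = `TRUE` when every O/E ratio and percentage matches
#'   (p-value mismatches at 4 significant figures are reported but do not
#'   clear the flag).
#' @examples
#' rep <- reproduceTables()
#' attr(rep, "ok")
#' @export
reproduceTables <- function(fixtureDir = NULL) {
    tabs <- if (is.null(fixtureDir)) referenceCountTables() else {
        out <- lapply(c("markerEnrichment", "enhancerEnrichment",
                        "hsrsOverlap", "survivalHsrs", "survivalScars",
                        "stemnessMatrix"),
                      function(nm) read.delim(
                          file.path(fixtureDir, paste0(nm, ".tsv"))))
        names(out) <- c("markerEnrichment", "enhancerEnrichment",
                        "hsrsOverlap", "survivalHsrs", "survivalScars",
                        "stemnessMatrix")
        out
    }
    rows <- list()
    add <- function(tid, lbl, metric, printed, recomputed, match) {
        rows[[length(rows) + 1L]] <<- data.frame(
            table_id = tid, row_label = lbl, metric = metric,
            printed = printed, recomputed = recomputed, match = match)
    }
    for (tab in list(tabs$markerEnrichment, tabs$enhancerEnrichment)) {
        for (i in seq_len(nrow(tab))) {
            r <- tab[i, ]
            res <- hypergeomOverlapTest(r$N, r$K, r$n, r$k)
            add(r$table_id, r$row_label, "oe", r$oe_printed,
                .roundHalfUp(res$oeRatio, 2L),
                .roundHalfUp(res$oeRatio, 2L) == r$oe_printed)
            pctDigits <- if (r$percent_printed == round(r$percent_printed, 1))
                1L else 2L
            pct <- .roundHalfUp(100 * r$k / r$n, pctDigits)
            add(r$table_id, r$row_label, "percent", r$percent_printed, pct,
                pct == r$percent_printed)
            add(r$table_id, r$row_label, "p", r$p_printed,
                signif(res$pPrinted, 4L),
                .signifEq(res$pPrinted, r$p_printed,
                          min(4L, .printedSigDigits(r$p_printed))))
        }
    }
    for (tab in list(tabs$hsrsOverlap, tabs$survivalHsrs,
                     tabs$survivalScars)) {
        pct <- .roundHalfUp(100 * tab$overlap / tab$total, 2L)
        for (i in seq_len(nrow(tab)))
            add(tab$table_id[i], tab$row_label[i], "percent",
                tab$percent_printed[i], pct[i],
                pct[i] == tab$percent_printed[i])
    }
    sm <- tabs$stemnessMatrix
    printedTotals <- attr(sm, "printedNodeTotals")
    if (is.null(printedTotals))
        printedTotals <- c(silenced = 1365, activated = 834)
    nodes <- stemnessNodes(sm)
    for (col in c("silenced", "activated"))
        add("stemness_matrix", "node_total", col,
            unname(printedTotals[[col]]), nodes[[col]],
            nodes[[col]] == printedTotals[[col]])
    report <- do.call(rbind, rows)
    hard <- report$metric %in% c("oe", "percent")
    attr(report, "ok") <- all(report$match[hard])
    report
}

## number of significant digits a printed p-value actually carries
.printedSigDigits <- function(p) {
    s <- sub("[eE].*$", "", format(p, scientific = TRUE))
    nchar(gsub("[^0-9]", "", sub("^0+", "", s)))
}
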