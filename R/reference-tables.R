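#' Published summary count tables for SCARS regulatory analyses
#'
#' Transcriptions of previously published summary tables that fully
#' parameterize the enrichment and overlap statistics this package
#' implements: lineage-marker enrichment among MLME up-regulated genes
#' (`markerEnrichment`), hESC enhancer-network enrichment of embryonic
#' lineage signatures (`enhancerEnrichment`), SCARS/HSRS overlap
#' percentage tables (`hsrsOverlap`, `survivalHsrs`, `survivalScars`) and
#' the cancer stemness matrix (`stemnessMatrix`).  They serve as printed
#' count fixtures: [reproduceTables()] replays them through the statistics
#' layer and compares the recomputed values with the published ones.
#'
#' Enrichment rows carry the hypergeometric parameters `(N, K, n, k)`
#' plus the published percent, p-value and observed/expected ratio.
#' The published p-values follow the point-probability convention
#' (see `vignette("scars-methods")`).
#'
#' @return A named list of data frames: `markerEnrichment`,
#'   `enhancerEnrichment`, `hsrsOverlap`, `survivalHsrs`, `survivalScars`,
#'   `stemnessMatrix`.
#' @examples
#' referenceCountTables()$markerEnrichment
#' @export
referenceCountTables <- function() {
    markerEnrichment <- data.frame(
        table_id = "marker_enrichment",
        row_label = c("EPI", "PE", "TE"),
        N = 26178L, K = 9430L,
        n = c(100L, 88L, 100L),
        k = c(91L, 41L, 81L),
        percent_printed = c(91.0, 46.6, 81.0),
        p_printed = c(1.186e-30, 0.0107581, 2.799e-20),
        oe_printed = c(2.53, 1.29, 2.25))

    networks <- c(naive = 18766L, primed = 17131L, combined = 25421L)
    ges <- rep(c("human_EPI_vs_naive_hESC", "human_EPI_vs_TE",
                 "monkey_EPI", "mouse_ICM_vs_TE"), each = 3L)
    enhancerEnrichment <- data.frame(
        table_id = "enhancer_enrichment",
        row_label = paste(ges, rep(names(networks), 4L), sep = "|"),
        N = 63677L,
        K = unname(rep(networks, 4L)),
        n = rep(c(1496L, 836L, 719L, 497L), each = 3L),
        k = c(762L, 726L, 976L,
              525L, 472L, 647L,
              442L, 399L, 529L,
              246L, 211L, 303L),
        percent_printed = c(50.9, 48.5, 65.2,
                            62.8, 56.5, 77.4,
                            61.5, 55.5, 73.6,
                            49.5, 42.5, 61.0),
        p_printed = c(1.544e-69, 5.669e-73, 4.326e-89,
                      1.176e-89, 2.095e-73, 2.11e-109,
                      1.665e-71, 1.687e-59, 1.003e-75,
                      2.533e-21, 2.314e-14, 1.061e-21),
        oe_printed = c(1.73, 1.80, 1.63,
                       2.13, 2.10, 1.94,
                       2.09, 2.06, 1.84,
                       1.68, 1.58, 1.53))

    hsrsOverlap <- data.frame(
        table_id = "hsrs_overlap",
        row_label = c("HERV-H lncRNA-regulated",
                      "LTR7Y/B enhancers-regulated",
                      "LTR5_Hs/SVA_D enhancers-regulated",
                      "ALL SCARS-regulated"),
        total = 13824L,
        overlap = c(4805L, 5240L, 2022L, 8384L),
        percent_printed = c(34.76, 37.91, 14.63, 60.65))

    cancers <- c("Thyroid", "Glioma", "Melanoma", "Head and neck",
                 "Colorectal", "Renal", "Ovarian", "Liver", "Lung",
                 "Breast", "Urothelial", "Stomach", "Prostate",
                 "Endometrial", "Cervical", "Pancreatic", "Testis", "ALL")
    survivalHsrs <- data.frame(
        table_id = "survival_hsrs",
        row_label = cancers,
        total = c(347L, 271L, 205L, 808L, 603L, 6070L, 504L, 2892L, 662L,
                  582L, 1101L, 307L, 161L, 1631L, 717L, 1549L, 60L,
                  10713L),
        overlap = c(269L, 206L, 153L, 597L, 440L, 4418L, 366L, 2086L,
                    477L, 414L, 783L, 218L, 114L, 1153L, 505L, 1075L,
                    42L, 7738L),
        percent_printed = c(77.52, 76.01, 74.63, 73.89, 72.97, 72.78,
                            72.62, 72.13, 72.05, 71.13, 71.12, 71.01,
                            70.81, 70.69, 70.43, 69.40, 70.00, 72.23))

    cancers4 <- c("Breast", "Prostate", "Pancreatic", "Liver", "Renal",
                  "Colorectal", "Cervical", "Lung", "Thyroid", "Ovarian",
                  "Endometrial", "Urothelial", "Head & Neck", "Glioma",
                  "Melanoma", "Stomach", "Testis", "ALL")
    survivalScars <- data.frame(
        table_id = "survival_scars",
        row_label = cancers4,
        total = c(582L, 161L, 1549L, 2892L, 6070L, 603L, 717L, 662L,
                  347L, 504L, 1631L, 1101L, 808L, 271L, 205L, 307L, 60L,
                  10713L),
        overlap = c(405L, 121L, 1112L, 2217L, 4406L, 448L, 526L, 488L,
                    259L, 368L, 1129L, 772L, 558L, 204L, 148L, 219L, 41L,
                    7609L),
        percent_printed = c(69.59, 75.16, 71.79, 76.66, 72.59, 74.30,
                            73.36, 73.72, 74.64, 73.02, 69.22, 70.12,
                            69.06, 75.28, 72.20, 71.34, 68.33, 71.03))

    stemnessMatrix <- data.frame(
        table_id = "stemness_matrix",
        cancerType = c("Adenoid Cystic", "Bladder", "Blood", "Brain",
                       "Breast", "Cervix", "Cholangiocarcinoma",
                       "Colorectal", "Endometrium", "Gastroesophageal",
                       "Head & Neck", "Kidney Clear", "Kidney Non-Clear",
                       "Liver", "Lung AD", "Lung SC", "Lymph", "Ovarian",
                       "Pancreas", "Pheochromocytoma", "Pleura",
                       "Prostate", "Sarcoma", "Skin",
                       "Testicular Germ Cell", "Thymus", "Thyroid",
                       "Uveal Melanoma"),
        silenced = c(7L, 30L, 25L, 28L, 28L, 12L, 8L, 16L, 30L, 37L, 19L,
                     8L, 14L, 18L, 15L, 7L, 36L, 4L, 22L, 5L, 9L, 19L,
                     6L, 21L, 11L, 7L, 8L, 2L),
        activated = c(4L, 16L, 22L, 16L, 17L, 8L, 4L, 12L, 20L, 26L, 6L,
                      5L, 6L, 10L, 9L, 3L, 25L, 2L, 17L, 3L, 0L, 11L, 3L,
                      13L, 8L, 2L, 9L, 1L))
    attr(stemnessMatrix, "printedNodeTotals") <-
        c(silenced = 1365L, activated = 834L)

    list(markerEnrichment = markerEnrichment,
         enhancerEnrichment = enhancerEnrichment,
         hsrsOverlap = hsrsOverlap,
         survivalHsrs = survivalHsrs,
         survivalScars = survivalScars,
         stemnessMatrix = stemnessMatrix)
}

#' Write the published count tables as tab-separated fixture files
#'
#' Emits one TSV per table of [referenceCountTables()] plus a combined
#' `enrichment_params.tsv` holding every `(table_id, row_label, N, K, n,
#' k)` quadruple, for consumption by [reproduceTables()] or external
#' tools.
#'
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeReferenceCountFixtures <- function(dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tabs <- referenceCountTables()
    for (nm in names(tabs))
        utils::write.table(tabs[[nm]],
                           file.path(dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    enr <- rbind(tabs$markerEnrichment[c("table_id", "row_label", "N",
                                         "K", "n", "k")],
                 tabs$enhancerEnrichment[c("table_id", "row_label", "N",
                                           "K", "n", "k")])
    utils::write.table(enr, file.path(dir, "enrichment_params.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
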