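#' @importFrom stats cor.test
NULL

## round half up to `digits` decimal places (table percentages and O/E
## ratios are printed with half-up rounding; base round() is half-even)
.roundHalfUp <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Category overlap table with percentages
#'
#' For each category set, counts its members, its overlap with a reference
#' set and the percentage `100 * overlap / total` rounded half-up to 2
#' decimal places, plus an `ALL` row over the union of all categories.
#'
#' @param categorySets named list of character vectors.
#' @param reference character vector (e.g. the SCARS-regulated genes).
#' @param allLabel label of the union row (default `"ALL"`; `NULL` skips
#'   the row).
#' @return A `data.frame` with columns `category`, `total`, `overlap`,
#'   `percent`.
#' @examples
#' overlapTable(list(A = c("g1", "g2")), reference = "g1")
#' @export
overlapTable <- function(categorySets, reference, allLabel = "ALL") {
    stopifnot(length(categorySets) > 0L, !is.null(names(categorySets)))
    reference <- unique(as.character(reference))
    categorySets <- lapply(categorySets, function(s) unique(as.character(s)))
    if (any(vapply(categorySets, length, 1L) == 0L))
        stop("category sets must be non-empty")
    if (!is.null(allLabel))
        categorySets[[allLabel]] <- unique(unlist(categorySets))
    total <- vapply(categorySets, length, 1L)
    overlap <- vapply(categorySets, function(s)
        length(intersect(s, reference)), 1L)
    data.frame(category = names(categorySets), total = total,
               overlap = overlap,
               percent = .roundHalfUp(100 * overlap / total, 2L),
               row.names = NULL)
}

#' Actionable node counts of a stemness matrix
#'
#' A stemness matrix maps each cancer type to counts of silenced and
#' activated driver genes; each (gene, cancer type) pair contributes one
#' node per regulator family, so the node count is the column sum times
#' the family count (default 3 families: HERV-H lncRNA, LTR7Y/B and
#' LTR5_Hs/SVA_D).
#'
#' @param matrixDf `data.frame` with numeric columns `silenced` and
#'   `activated` (one row per cancer type).
#' @param familyCount number of regulator families (default 3).
#' @return A list with `silenced` and `activated` node counts.
#' @export
stemnessNodes <- function(matrixDf, familyCount = 3L) {
    stopifnot(is.data.frame(matrixDf),
              all(c("silenced", "activated") %in% colnames(matrixDf)),
              familyCount >= 1L)
    if (any(matrixDf$silenced < 0) || any(matrixDf$activated < 0))
        stop("gene counts must be non-negative")
    list(silenced = sum(matrixDf$silenced) * familyCount,
         activated = sum(matrixDf$activated) * familyCount)
}

#' Pearson correlation with Bonferroni-adjusted p-value
#'
#' Standard Pearson correlation with the two-sided t-transform p-value on
#' `length(x) - 2` degrees of freedom; the Bonferroni adjustment
#' `min(1, m * p)` accounts for `m` parallel correlation tests.
#'
#' @param x,y numeric vectors of equal length (at least 3 finite pairs).
#' @param m number of tests in the family (default 1).
#' @return A list with `r`, `pNominal` and `pBonferroni`.
#' @examples
#' pearsonWithBonferroni(1:10, 2 * (1:10) + 1)
#' @export
pearsonWithBonferroni <- function(x, y, m = 1L) {
    stopifnot(length(x) == length(y), length(x) >= 3L,
              all(is.finite(x)), all(is.finite(y)), m >= 1L)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in x or y")
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), pNominal = ct$p.value,
         pBonferroni = min(1, m * ct$p.value))
}

#' Attribute cancer deaths to SCARS-associated malignancies
#'
#' Given per-cancer prevalence of SCARS-associated malignancies and
#' annual incidence/mortality, computes attributed cases
#' `prevalencePct/100 * newCases` and attributed deaths capped at the
#' total deaths for that cancer type (the cap makes the attribution a
#' maximum estimate that never exceeds the estimated deaths).
#'
#' @param records `data.frame` with columns `cancerType`, `prevalencePct`
#'   (in `[0, 100]`), `newCases` and `deaths` (counts per year).
#' @return A list with `records` (input plus `attributedCases` and
#'   `attributedDeaths`) and `summary` (totals and the percent of all
#'   deaths attributed).
#' @examples
#' mortalityAttribution(data.frame(cancerType = "x", prevalencePct = 50,
#'                                 newCases = 1000, deaths = 800))
#' @export
mortalityAttribution <- function(records) {
    need <- c("cancerType", "prevalencePct", "newCases", "deaths")
    stopifnot(is.data.frame(records), all(need %in% colnames(records)))
    if (any(records$prevalencePct < 0 | records$prevalencePct > 100))
        stop("prevalencePct must lie in [0, 100]")
    if (any(records$newCases < 0) || any(records$deaths < 0))
        stop("newCases and deaths must be non-negative")
    out <- records
    out$attributedCases <- out$prevalencePct / 100 * out$newCases
    out$attributedDeaths <- pmin(out$attributedCases, out$deaths)
    list(records = out,
         summary = list(
             totalDeaths = sum(out$deaths),
             totalAttributedDeaths = sum(out$attributedDeaths),
             percentDeathsAttributed = if (sum(out$deaths) > 0)
                 .roundHalfUp(100 * sum(out$attributedDeaths) /
                                  sum(out$deaths), 2L) else NA_real_))
}
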