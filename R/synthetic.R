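#' @importFrom stats rnorm runif
NULL

#' Configuration for the synthetic single-cell expression generator
#'
#' Defaults emulate the published study conditions: 839 telomerase-positive
#' embryonic cells containing 135 planted MLME cells, validation marker
#' panels of 100 (EPI), 100 (TE) and 88 (PE) genes plus the pluripotency
#' trio and TERT.  The generative model is the package's own (no model is
#' published) and is documented in `vignette("scars-methods")`: lineage
#' markers, trio and TERT are transcribed only in cells of a matching role;
#' transcribed values are log-normal `exp(N(markerEffect, noiseSd))`;
#' technical dropout zeroes a transcribed value with probability
#' `dropoutRate * exp(-markerEffect)` (dropout decays with expression
#' level); non-transcribed marker genes observe 0 except for a small
#' technical leakage; background genes are log-normal
#' `exp(N(0, noiseSd))` with dropout `dropoutRate` in every cell.
#'
#' @param nCells number of cells (default 839).
#' @param nGenes total genes including panels, trio, TERT and background
#'   filler genes (default 2000).
#' @param nMlme number of planted MLME cells (default 135).
#' @param panelSizes named integer vector `c(EPI=, TE=, PE=)`; a 58-marker
#'   discovery-style panel can be emulated by shrinking these.
#' @param markerEffect log-scale expression shift of transcribed markers
#'   (default 3).
#' @param noiseSd log-scale noise standard deviation (default 1).
#' @param dropoutRate baseline technical dropout probability (default 0.1).
#' @param leakageRate probability that a non-transcribed marker gene still
#'   observes a baseline-level value (default 0.05).
#' @param lineageFractions fractions of the non-MLME cells committed to
#'   each lineage (default `c(EPI=0.2, TE=0.5, PE=0.15)`; the remainder are
#'   background cells expressing no markers).
#' @param criteria the [MLMECriteria] whose minima the planted marker
#'   counts must reach; panels smaller than the minima are rejected.
#' @param seed integer seed; all generator randomness flows from it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nCells = 839L, nGenes = 2000L, nMlme = 135L,
                             panelSizes = c(EPI = 100L, TE = 100L, PE = 88L),
                             markerEffect = 3, noiseSd = 1,
                             dropoutRate = 0.1, leakageRate = 0.05,
                             lineageFractions = c(EPI = 0.2, TE = 0.5,
                                                  PE = 0.15),
                             criteria = MLMECriteria(), seed = 1L) {
    cfg <- list(nCells = as.integer(nCells), nGenes = as.integer(nGenes),
                nMlme = as.integer(nMlme),
                panelSizes = vapply(panelSizes, as.integer, 1L),
                markerEffect = markerEffect, noiseSd = noiseSd,
                dropoutRate = dropoutRate, leakageRate = leakageRate,
                lineageFractions = lineageFractions, criteria = criteria,
                seed = as.integer(seed))
    if (cfg$nCells < 2L) stop("nCells must be >= 2")
    if (cfg$nMlme < 0L || cfg$nMlme > cfg$nCells)
        stop("nMlme must lie in [0, nCells]")
    if (!all(c("EPI", "TE", "PE") %in% names(cfg$panelSizes)))
        stop("panelSizes must name EPI, TE and PE")
    minima <- c(EPI = criteria@minEpi, TE = criteria@minTe,
                PE = criteria@minPe)
    low <- cfg$panelSizes[names(minima)] < minima
    if (any(low))
        stop("panel size(s) below the classifier minima: ",
             paste(names(minima)[low], collapse = ", "))
    probs <- c(cfg$markerEffect > 0, cfg$noiseSd >= 0,
               cfg$dropoutRate >= 0 && cfg$dropoutRate <= 1,
               cfg$leakageRate >= 0 && cfg$leakageRate <= 1)
    if (!all(probs))
        stop("markerEffect must be > 0; rates must lie in [0, 1]")
    if (any(cfg$lineageFractions < 0) || sum(cfg$lineageFractions) > 1)
        stop("lineageFractions must be non-negative and sum to <= 1")
    if (cfg$nGenes < sum(cfg$panelSizes) + 4L)
        stop("nGenes must accommodate the panels, the trio and TERT")
    class(cfg) <- "SimulationConfig"
    cfg
}

## sample a planted marker count in [minimum, panel size]
.plantCount <- function(minimum, size) {
    if (minimum == size) minimum else sample(minimum:size, 1L)
}

#' Generate a synthetic expression matrix with planted MLME cells
#'
#' Produces a genes-by-cells matrix of non-negative values in which
#' `nMlme` planted cells carry the full MLME pattern (at least the
#' per-lineage minimum of randomly chosen markers from every panel, the
#' trio and TERT transcribed), committed lineage cells transcribe markers
#' of their own lineage only, and background cells transcribe no markers.
#' Under zero noise (`noiseSd = 0`, `dropoutRate = 0`, `leakageRate = 0`)
#' the planted labels are exactly recoverable by
#' [expressionCalls()] + [classifyMLME()].
#'
#' @param config a [simulationConfig()].
#' @return A `SummarizedExperiment` with assay `expr`, `colData(se)$role`
#'   (`"MLME"`, `"EPI-only"`, `"TE-only"`, `"PE-only"`, `"background"`),
#'   `rowData(se)$panel` membership, and `metadata(se)` entries `panels`
#'   (the [MarkerPanelSet]), `truth` (planted cell ids and per-cell planted
#'   marker lists) and `config`.
#' @examples
#' se <- generateExpressionMatrix(simulationConfig(nCells = 50, nMlme = 5,
#'     nGenes = 300, seed = 1))
#' table(SummarizedExperiment::colData(se)$role)
#' @export
generateExpressionMatrix <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    sizes <- config$panelSizes
    panels <- MarkerPanelSet(
        epi = sprintf("EPIm%03d", seq_len(sizes[["EPI"]])),
        te = sprintf("TEm%03d", seq_len(sizes[["TE"]])),
        pe = sprintf("PEm%03d", seq_len(sizes[["PE"]])))
    special <- panelGenes(panels)
    nBg <- config$nGenes - length(special)
    genes <- c(special, sprintf("BG%05d", seq_len(nBg)))
    cells <- sprintf("cell%04d", seq_len(config$nCells))

    ## cell roles: planted MLME first in count, positions randomised
    nLin <- round(config$lineageFractions * (config$nCells - config$nMlme))
    roles <- sample(rep(c("MLME", "EPI-only", "TE-only", "PE-only",
                          "background"),
                        c(config$nMlme, nLin[["EPI"]], nLin[["TE"]],
                          nLin[["PE"]],
                          config$nCells - config$nMlme - sum(nLin))))

    panelList <- list(EPI = panels@epi, TE = panels@te, PE = panels@pe)
    minima <- c(EPI = config$criteria@minEpi, TE = config$criteria@minTe,
                PE = config$criteria@minPe)

    ## transcription (on/off) states for the marker genes
    on <- matrix(FALSE, length(special), config$nCells,
                 dimnames = list(special, cells))
    planted <- vector("list", config$nCells)
    names(planted) <- cells
    for (ci in seq_len(config$nCells)) {
        r <- roles[ci]
        if (r == "background") { planted[[ci]] <- character(0); next }
        lineages <- if (r == "MLME") c("EPI", "TE", "PE") else
            sub("-only", "", r)
        mine <- unlist(lapply(lineages, function(l)
            sample(panelList[[l]], .plantCount(minima[[l]],
                                               length(panelList[[l]])))))
        if (r == "MLME")
            mine <- c(mine, panels@trio, panels@telomeraseGene)
        on[mine, ci] <- TRUE
        planted[[ci]] <- mine
    }

    vals <- matrix(0, length(special), config$nCells,
                   dimnames = list(special, cells))
    nOn <- sum(on)
    onVals <- exp(rnorm(nOn, config$markerEffect, config$noiseSd))
    onVals[runif(nOn) < config$dropoutRate * exp(-config$markerEffect)] <- 0
    vals[on] <- onVals
    nOff <- sum(!on)
    leak <- runif(nOff) < config$leakageRate
    offVals <- numeric(nOff)
    offVals[leak] <- exp(rnorm(sum(leak), 0, config$noiseSd))
    vals[!on] <- offVals

    bg <- matrix(exp(rnorm(nBg * config$nCells, 0, config$noiseSd)),
                 nBg, config$nCells,
                 dimnames = list(genes[-seq_along(special)], cells))
    bg[matrix(runif(length(bg)) < config$dropoutRate, nrow(bg))] <- 0

    m <- rbind(vals, bg)
    panelOf <- c(rep(c("EPI", "TE", "PE"), sizes[c("EPI", "TE", "PE")]),
                 rep("trio", 3L), "telomerase", rep("background", nBg))
    se <- SummarizedExperiment(
        assays = list(expr = m),
        rowData = DataFrame(panel = panelOf, row.names = genes),
        colData = DataFrame(role = roles, row.names = cells))
    metadata(se) <- list(
        panels = panels, config = config,
        truth = list(mlmeCells = cells[roles == "MLME"],
                     roles = stats::setNames(roles, cells),
                     plantedMarkers = planted))
    se
}

#' Generate gene/element interval fixtures with planted proximity structure
#'
#' Places `nElements` regulatory elements uniformly on a synthetic genome
#' and then places exactly `round(plantedFraction * nGenes)` genes at a gap
#' of at most `window` bp from some element and the remaining genes at a
#' gap greater than `window` from every element, so the proximity map is
#' known by construction.
#'
#' @param nGenes,nElements interval counts.
#' @param plantedFraction fraction of genes planted within the window.
#' @param genomeLength synthetic genome length in bp.
#' @param window association window in bp (default 10000).
#' @param geneWidth,elementWidth interval widths in bp.
#' @param nChrom number of equally sized synthetic chromosomes.
#' @param seed integer seed.
#' @return A list with `genes` and `elements` (`GRanges` with `name`
#'   metadata) and `truth$associatedGenes` (ids of the planted genes).
#' @export
generateGenomeFixture <- function(nGenes = 1000L, nElements = 200L,
                                  plantedFraction = 0.3,
                                  genomeLength = 1e8, window = 10000,
                                  geneWidth = 5000, elementWidth = 1000,
                                  nChrom = 1L, seed = 1L) {
    stopifnot(plantedFraction >= 0, plantedFraction <= 1, nChrom >= 1L)
    set.seed(as.integer(seed))
    chromLen <- floor(genomeLength / nChrom)
    if (chromLen < geneWidth + elementWidth + 2 * window + 2)
        stop("infeasible packing: genome too short for the requested intervals")
    chroms <- sprintf("chrS%d", seq_len(nChrom))

    ## elements: uniform 0-based starts per chromosome
    eChrom <- sample(chroms, nElements, replace = TRUE)
    eStart <- floor(runif(nElements, 0, chromLen - elementWidth))
    elements <- GRanges(eChrom, IRanges(eStart + 1, eStart + elementWidth))
    mcols(elements)$name <- sprintf("elem%04d", seq_len(nElements))
    names(elements) <- mcols(elements)$name

    nNear <- round(plantedFraction * nGenes)
    gChrom <- character(nGenes); gStart <- numeric(nGenes)

    ## planted genes: random element, random side, gap uniform in [0, window]
    if (nNear > 0) {
        if (nElements == 0)
            stop("infeasible packing: planted genes require elements")
        ei <- sample(nElements, nNear, replace = TRUE)
        gap <- floor(runif(nNear, 0, window + 1))
        right <- runif(nNear) < 0.5
        s <- ifelse(right, eStart[ei] + elementWidth + gap,
                    eStart[ei] - gap - geneWidth)
        flip <- s < 0 | s > chromLen - geneWidth
        s[flip] <- ifelse(right[flip],
                          eStart[ei[flip]] - gap[flip] - geneWidth,
                          eStart[ei[flip]] + elementWidth + gap[flip])
        bad <- s < 0 | s > chromLen - geneWidth
        if (any(bad))
            stop("infeasible packing: an element admits no in-bounds gene placement")
        gChrom[seq_len(nNear)] <- eChrom[ei]
        gStart[seq_len(nNear)] <- s
    }

    ## distant genes: sample uniformly from the complement of the forbidden
    ## start ranges [eStart - window - geneWidth, eEnd + window] per chromosome
    if (nNear < nGenes) {
        nFar <- nGenes - nNear
        allowed <- lapply(chroms, function(ch) {
            idx <- which(eChrom == ch)
            forb <- IRanges(pmax(0, eStart[idx] - window - geneWidth) + 1,
                            pmin(chromLen, eStart[idx] + elementWidth +
                                     window))
            IRanges::setdiff(IRanges(1, chromLen - geneWidth + 1),
                             IRanges::reduce(forb))
        })
        segs <- do.call(rbind, lapply(seq_along(chroms), function(i) {
            a <- allowed[[i]]
            if (length(a) == 0L) return(NULL)
            data.frame(chrom = chroms[i], lo = IRanges::start(a),
                       len = IRanges::width(a))
        }))
        if (is.null(segs) || sum(segs$len) == 0)
            stop("infeasible packing: no placement farther than the window from every element")
        seg <- sample(nrow(segs), nFar, replace = TRUE,
                      prob = segs$len / sum(segs$len))
        s1 <- segs$lo[seg] + floor(runif(nFar, 0, segs$len[seg]))  # 1-based
        gChrom[nNear + seq_len(nFar)] <- segs$chrom[seg]
        gStart[nNear + seq_len(nFar)] <- s1 - 1
    }

    genes <- GRanges(gChrom, IRanges(gStart + 1, gStart + geneWidth))
    mcols(genes)$name <- sprintf("gene%05d", seq_len(nGenes))
    names(genes) <- mcols(genes)$name
    list(genes = genes, elements = elements,
         truth = list(associatedGenes = mcols(genes)$name[seq_len(nNear)]))
}

#' Generate a gene-set library with planted overlap enrichment
#'
#' The first `enrichedSetCount` sets sample their members with sampling
#' weight `enrichmentOdds` for members of `targetSet` (1 for everything
#' else); the remaining sets sample uniformly from the universe.
#'
#' @param universe character vector of candidate member genes.
#' @param nSets number of sets.
#' @param setSizeRange integer pair; sizes are drawn uniformly in range.
#' @param targetSet genes to enrich for (must be a subset of `universe`).
#' @param enrichedSetCount how many sets are planted as enriched.
#' @param enrichmentOdds sampling-odds multiplier (1 = no enrichment).
#' @param seed integer seed.
#' @return A list with `library` (a [GeneSetLibrary]) and
#'   `truth$enrichedSets` (names of the planted sets).
#' @export
generateGeneSetLibrary <- function(universe, nSets = 100L,
                                   setSizeRange = c(50L, 200L),
                                   targetSet = character(0),
                                   enrichedSetCount = 0L,
                                   enrichmentOdds = 1, seed = 1L) {
    universe <- unique(as.character(universe))
    stopifnot(enrichedSetCount >= 0L, enrichedSetCount <= nSets,
              enrichmentOdds > 0)
    if (length(setdiff(targetSet, universe)))
        stop("targetSet must be a subset of the universe")
    if (max(setSizeRange) > length(universe))
        stop("set sizes must not exceed the universe size")
    set.seed(as.integer(seed))
    w <- ifelse(universe %in% targetSet, enrichmentOdds, 1)
    nm <- sprintf("SET_%04d", seq_len(nSets))
    sets <- lapply(seq_len(nSets), function(i) {
        size <- sample(setSizeRange[1L]:setSizeRange[2L], 1L)
        if (i <= enrichedSetCount)
            sample(universe, size, prob = w)
        else
            sample(universe, size)
    })
    names(sets) <- nm
    lib <- GeneSetLibrary(sets, rep("synthetic", nSets))
    list(library = lib,
         truth = list(enrichedSets = nm[seq_len(enrichedSetCount)]))
}
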