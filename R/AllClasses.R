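#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Marker panels defining the MLME phenotype
#'
#' Bundles the lineage marker panels of the three major preimplantation
#' lineages (epiblast, trophectoderm, primitive endoderm) together with the
#' pluripotency trio and the telomerase gene.  A cell is called MLME
#' (multi-lineage markers expressing) when it expresses at least a minimum
#' number of markers from every panel plus the trio and telomerase (see
#' [classifyMLME()]).
#'
#' The pluripotency trio appears in the literature both as OCT4/NANOG/SOX2
#' and as NANOG/POU5F1/SOX2; since OCT4 and POU5F1 are the same gene, the
#' default symbols are NANOG, POU5F1, SOX2 and the alias OCT4 -> POU5F1 is
#' resolved at construction.
#'
#' @slot epi,te,pe character vectors of marker gene identifiers for the
#'   epiblast, trophectoderm and primitive endoderm panels.
#' @slot trio exactly three pluripotency master regulator genes.
#' @slot telomeraseGene single telomerase gene identifier.
#' @export
setClass("MarkerPanelSet",
    representation(epi = "character", te = "character", pe = "character",
                   trio = "character", telomeraseGene = "character"))

setValidity("MarkerPanelSet", function(object) {
    msg <- character(0)
    if (length(object@trio) != 3L || anyDuplicated(object@trio))
        msg <- c(msg, "trio must contain exactly 3 distinct genes")
    if (length(object@telomeraseGene) != 1L)
        msg <- c(msg, "telomeraseGene must be a single identifier")
    for (p in c("epi", "te", "pe"))
        if (length(slot(object, p)) == 0L)
            msg <- c(msg, sprintf("%s panel must be non-empty", p))
    all <- c(object@epi, object@te, object@pe, object@trio,
             object@telomeraseGene)
    if (anyDuplicated(all))
        msg <- c(msg, sprintf(
            "panels, trio and telomerase gene must be mutually disjoint (duplicated: %s)",
            paste(unique(all[duplicated(all)]), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Gene symbol aliases resolved at panel construction
#' @noRd
.GENE_ALIASES <- c(OCT4 = "POU5F1")

.applyAliases <- function(x) {
    hit <- x %in% names(.GENE_ALIASES)
    x[hit] <- unname(.GENE_ALIASES[x[hit]])
    x
}

#' @rdname MarkerPanelSet-class
#' @param epi,te,pe marker gene identifiers per lineage panel.
#' @param trio the three pluripotency master regulators.
#' @param telomeraseGene the telomerase gene identifier.
#' @return A `MarkerPanelSet` object.
#' @examples
#' MarkerPanelSet(epi = paste0("EPI", 1:6), te = paste0("TE", 1:7),
#'                pe = paste0("PE", 1:4))
#' @export
MarkerPanelSet <- function(epi, te, pe,
                           trio = c("NANOG", "POU5F1", "SOX2"),
                           telomeraseGene = "TERT") {
    new("MarkerPanelSet",
        epi = .applyAliases(as.character(epi)),
        te = .applyAliases(as.character(te)),
        pe = .applyAliases(as.character(pe)),
        trio = .applyAliases(as.character(trio)),
        telomeraseGene = .applyAliases(as.character(telomeraseGene)))
}

#' @describeIn MarkerPanelSet-class all genes referenced by the panel set.
#' @param object,x a `MarkerPanelSet`.
#' @export
panelGenes <- function(object) {
    c(object@epi, object@te, object@pe, object@trio, object@telomeraseGene)
}

setMethod("show", "MarkerPanelSet", function(object) {
    cat("MarkerPanelSet\n")
    cat(sprintf("  EPI: %d markers; TE: %d; PE: %d\n",
                length(object@epi), length(object@te), length(object@pe)))
    cat(sprintf("  trio: %s; telomerase: %s\n",
                paste(object@trio, collapse = ", "), object@telomeraseGene))
})

#' Thresholds of the MLME classification rule
#'
#' The MLME phenotype is assigned to telomerase-positive cells that
#' co-express at least `minEpi` epiblast markers, `minTe` trophectoderm
#' markers and `minPe` primitive endoderm markers, and express all three
#' pluripotency trio genes.  Defaults are the published thresholds 6/7/4.
#'
#' @slot minEpi,minTe,minPe integer marker-count thresholds per lineage.
#' @slot requireTrio,requireTelomerase logical gates for the pluripotency
#'   trio and the telomerase call.
#' @export
setClass("MLMECriteria",
    representation(minEpi = "integer", minTe = "integer", minPe = "integer",
                   requireTrio = "logical", requireTelomerase = "logical"))

setValidity("MLMECriteria", function(object) {
    m <- c(object@minEpi, object@minTe, object@minPe)
    if (any(is.na(m)) || any(m < 1L))
        return("marker-count minima must be >= 1")
    TRUE
})

#' @rdname MLMECriteria-class
#' @param minEpi,minTe,minPe integer thresholds (defaults 6, 7, 4).
#' @param requireTrio,requireTelomerase logical gates (default `TRUE`).
#' @return An `MLMECriteria` object.
#' @export
MLMECriteria <- function(minEpi = 6L, minTe = 7L, minPe = 4L,
                         requireTrio = TRUE, requireTelomerase = TRUE) {
    new("MLMECriteria", minEpi = as.integer(minEpi), minTe = as.integer(minTe),
        minPe = as.integer(minPe), requireTrio = requireTrio,
        requireTelomerase = requireTelomerase)
}

setMethod("show", "MLMECriteria", function(object) {
    cat(sprintf("MLMECriteria: EPI >= %d, TE >= %d, PE >= %d, trio=%s, telomerase=%s\n",
                object@minEpi, object@minTe, object@minPe,
                object@requireTrio, object@requireTelomerase))
})

#' A named library of gene sets
#'
#' Thin container for GMT-style gene-set libraries: a named list of
#' de-duplicated member vectors plus one description per set.
#'
#' @slot sets named list of character vectors (members, de-duplicated).
#' @slot descriptions character vector parallel to `sets`.
#' @export
setClass("GeneSetLibrary",
    representation(sets = "list", descriptions = "character"))

setValidity("GeneSetLibrary", function(object) {
    msg <- character(0)
    nm <- names(object@sets)
    if (is.null(nm) || any(!nzchar(nm)))
        msg <- c(msg, "all gene sets must be named")
    if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicate set names: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "descriptions must parallel sets")
    if (any(vapply(object@sets, length, 1L) == 0L))
        msg <- c(msg, "gene sets must be non-empty")
    if (any(vapply(object@sets, anyDuplicated, 1L) > 0L))
        msg <- c(msg, "gene set members must be de-duplicated")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneSetLibrary-class
#' @param sets named list of character vectors of member genes.  Duplicate
#'   members within a set are collapsed with a warning.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A `GeneSetLibrary`.
#' @export
GeneSetLibrary <- function(sets, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("", length(sets))
    ndup <- vapply(sets, anyDuplicated, 1L)
    if (any(ndup > 0L)) {
        warning(sprintf("collapsing duplicate members in set(s): %s",
                paste(names(sets)[ndup > 0L], collapse = ", ")))
        sets <- lapply(sets, unique)
    }
    new("GeneSetLibrary", sets = lapply(sets, as.character),
        descriptions = as.character(descriptions))
}

#' @describeIn GeneSetLibrary-class number of gene sets.
#' @export
setMethod("length", "GeneSetLibrary", function(x) length(x@sets))

#' @describeIn GeneSetLibrary-class set names.
#' @export
setMethod("names", "GeneSetLibrary", function(x) names(x@sets))

#' @describeIn GeneSetLibrary-class extract one member vector by name/index.
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSetLibrary", function(x, i) x@sets[[i]])

#' @describeIn GeneSetLibrary-class the member lists as a plain named list.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetLibrary-class per-set descriptions.
#' @export
setDescriptions <- function(x) {
    stats::setNames(x@descriptions, names(x@sets))
}

setMethod("show", "GeneSetLibrary", function(object) {
    sz <- vapply(object@sets, length, 1L)
    cat(sprintf("GeneSetLibrary with %d sets (member counts %d-%d)\n",
                length(object@sets),
                if (length(sz)) min(sz) else 0L,
                if (length(sz)) max(sz) else 0L))
})

#' Element-to-gene proximity associations
#'
#' Result of [associateGenes()]: every (element, gene) pair on the same
#' chromosome whose interval gap is at most `window` base pairs, together
#' with the gap.  Overlapping intervals have gap 0.
#'
#' @slot hits `DataFrame` with columns `element_id`, `gene_id`, `gap`.
#' @slot window the association window in bp.
#' @slot anchor `"body"` (whole gene interval) or `"tss"`.
#' @slot nElements,nGenes sizes of the input interval sets.
#' @export
setClass("ProximityMap",
    representation(hits = "DataFrame", window = "numeric", anchor = "character",
                   nElements = "integer", nGenes = "integer"))

setValidity("ProximityMap", function(object) {
    msg <- character(0)
    need <- c("element_id", "gene_id", "gap")
    if (!all(need %in% colnames(object@hits)))
        msg <- c(msg, "hits must have columns element_id, gene_id, gap")
    else if (nrow(object@hits) && any(object@hits$gap > object@window))
        msg <- c(msg, "all association gaps must be <= window")
    if (length(msg)) msg else TRUE
})

#' @describeIn ProximityMap-class the association table.
#' @param x a `ProximityMap`.
#' @export
proximityHits <- function(x) x@hits

setMethod("show", "ProximityMap", function(object) {
    cat(sprintf(
        "ProximityMap: %d associations (%d elements x %d genes, window %g bp, anchor '%s')\n",
        nrow(object@hits), object@nElements, object@nGenes,
        object@window, object@anchor))
})
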