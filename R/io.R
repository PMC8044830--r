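#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom GenomicRanges GRanges strand seqnames start end width
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges
NULL

## ---- expression matrices ------------------------------------------------

.validateExpressionValues <- function(m) {
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("expression matrix must carry gene (row) and cell (column) ids")
    dup <- rownames(m)[duplicated(rownames(m))]
    if (length(dup))
        stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
    dup <- colnames(m)[duplicated(colnames(m))]
    if (length(dup))
        stop("duplicate cell id(s): ", paste(unique(dup), collapse = ", "))
    if (!is.numeric(m))
        stop("expression values must be numeric")
    if (any(!is.finite(m)))
        stop("expression values must be finite")
    if (any(m < 0))
        stop("expression values must be non-negative")
    invisible(m)
}

#' Read / write an expression matrix as TSV
#'
#' Tab-separated layout: header row of cell identifiers, one row per gene
#' with the gene identifier in the first column.  Values are serialized at
#' full double precision so that `readExpressionTsv(writeExpressionTsv(x))`
#' reproduces `x` exactly.
#'
#' @param path file path.
#' @return `readExpressionTsv` returns a
#'   [SummarizedExperiment::SummarizedExperiment] with one assay `"expr"`;
#'   `writeExpressionTsv` returns `path` invisibly.
#' @examples
#' se <- SummarizedExperiment::SummarizedExperiment(
#'     assays = list(expr = matrix(1:4, 2, 2,
#'         dimnames = list(c("g1", "g2"), c("c1", "c2")))))
#' f <- tempfile()
#' writeExpressionTsv(se, f)
#' readExpressionTsv(f)
#' @export
readExpressionTsv <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) < 2L)
        stop("expression TSV must have a header and at least one gene row")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    header <- parts[[1L]]
    cells <- header[-1L]
    nfield <- length(header)
    body <- parts[-1L]
    bad <- which(vapply(body, length, 1L) != nfield)
    if (length(bad))
        stop("ragged row(s) at line(s): ",
             paste(bad + 1L, collapse = ", "))
    genes <- vapply(body, `[[`, "", 1L)
    vals <- vapply(body, function(p) {
        v <- suppressWarnings(as.numeric(p[-1L]))
        if (anyNA(v))
            stop("non-numeric value in row for gene '", p[[1L]], "'")
        v
    }, numeric(length(cells)))
    m <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(cells))
    dimnames(m) <- list(genes, cells)
    .validateExpressionValues(m)
    SummarizedExperiment(assays = list(expr = m))
}

.exprMatrix <- function(x) {
    m <- if (methods::is(x, "SummarizedExperiment")) assay(x) else x
    m <- as.matrix(m)
    .validateExpressionValues(m)
    m
}

#' @rdname readExpressionTsv
#' @param x a `SummarizedExperiment` (first assay is written) or a numeric
#'   matrix with gene/cell dimnames.
#' @export
writeExpressionTsv <- function(x, path) {
    m <- .exprMatrix(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t"),
        "")
    writeLines(body, con)
    invisible(path)
}

#' Read / write an expression matrix as sparse matrix-market triplets
#'
#' Writes three files under `prefix`: `<prefix>.mtx` (MatrixMarket triplet),
#' `<prefix>.genes.txt` and `<prefix>.cells.txt` (one identifier per line).
#'
#' @param prefix path prefix for the three files.
#' @inheritParams readExpressionTsv
#' @return `readExpressionMM` returns a `SummarizedExperiment`;
#'   `writeExpressionMM` returns `prefix` invisibly.
#' @export
writeExpressionMM <- function(x, prefix) {
    m <- .exprMatrix(x)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"),
                    paste0(prefix, ".mtx"))
    writeLines(rownames(m), paste0(prefix, ".genes.txt"))
    writeLines(colnames(m), paste0(prefix, ".cells.txt"))
    invisible(prefix)
}

#' @rdname writeExpressionMM
#' @export
readExpressionMM <- function(prefix) {
    sm <- Matrix::readMM(paste0(prefix, ".mtx"))
    genes <- readLines(paste0(prefix, ".genes.txt"))
    cells <- readLines(paste0(prefix, ".cells.txt"))
    if (nrow(sm) != length(genes) || ncol(sm) != length(cells))
        stop("matrix dimensions do not match gene/cell id files")
    m <- as.matrix(sm)
    dimnames(m) <- list(genes, cells)
    .validateExpressionValues(m)
    SummarizedExperiment(assays = list(expr = m))
}

## ---- BED intervals ------------------------------------------------------

#' Read / write BED intervals as GRanges
#'
#' BED convention: 0-based half-open coordinates on disk, converted to the
#' 1-based closed convention of [GenomicRanges::GRanges] in memory.  At
#' least 4 tab-separated columns (chrom, start, end, name) are required;
#' columns 5 (score) and 6 (strand) are honoured when present.  Missing
#' strand becomes `"*"` (written back as `"."`).
#'
#' @param path file path.
#' @param oneBased set `TRUE` if the input file uses 1-based inclusive
#'   coordinates; they are converted to BED convention at the boundary.
#' @return `readBed` returns a `GRanges` with metadata columns `name` and
#'   `score`; `writeBed` returns `path` invisibly and round-trips
#'   `readBed` output byte-identically.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\te1", f)
#' readBed(f)
#' @export
readBed <- function(path, oneBased = FALSE) {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineno <- which(keep)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    n <- vapply(parts, length, 1L)
    if (any(n < 4L))
        stop("BED line(s) with fewer than 4 fields at line(s): ",
             paste(lineno[n < 4L], collapse = ", "))
    chrom <- vapply(parts, `[[`, "", 1L)
    s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    e <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    id <- vapply(parts, `[[`, "", 4L)
    bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
    if (any(bad))
        stop("non-integer coordinates at line(s): ",
             paste(lineno[bad], collapse = ", "))
    if (oneBased) s <- s - 1
    bad <- s < 0
    if (any(bad))
        stop("negative start coordinate at line(s): ",
             paste(lineno[bad], collapse = ", "))
    bad <- s >= e
    if (any(bad))
        stop("start >= end at line(s): ", paste(lineno[bad], collapse = ", "))
    score <- ifelse(n >= 5L, vapply(parts, function(p)
        if (length(p) >= 5L) p[[5L]] else "0", ""), "0")
    strand <- ifelse(n >= 6L, vapply(parts, function(p)
        if (length(p) >= 6L) p[[6L]] else ".", ""), ".")
    bad <- !strand %in% c("+", "-", ".")
    if (any(bad))
        stop("invalid strand at line(s): ", paste(lineno[bad], collapse = ", "))
    gr <- GRanges(chrom, IRanges(s + 1, e),
                  strand = ifelse(strand == ".", "*", strand))
    mcols(gr)$name <- id
    mcols(gr)$score <- suppressWarnings(as.numeric(score))
    names(gr) <- id
    gr
}

#' @rdname readBed
#' @param gr a `GRanges`; interval ids are taken from `mcols(gr)$name` or
#'   `names(gr)`.
#' @export
writeBed <- function(gr, path) {
    id <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else names(gr)
    if (is.null(id))
        stop("intervals must carry ids in mcols(gr)$name or names(gr)")
    score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else
        rep(0, length(gr))
    score[is.na(score)] <- 0
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                       as.character(seqnames(gr)),
                       start(gr) - 1L, end(gr), id, score, str), path)
    invisible(path)
}

## ---- GMT gene-set libraries --------------------------------------------

#' Read / write gene-set libraries in GMT format
#'
#' One set per line: name, description, then tab-separated members.
#' Duplicate members within a set are collapsed with a warning; duplicate
#' set names are an error.
#'
#' @param path file path.
#' @return `readGmt` returns a [GeneSetLibrary]; `writeGmt` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("setA\tdemo\tg1\tg2", f)
#' readGmt(f)
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    keep <- nzchar(lines)
    lineno <- which(keep)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    n <- vapply(parts, length, 1L)
    if (any(n < 3L))
        stop("GMT line(s) without members at line(s): ",
             paste(lineno[n < 3L], collapse = ", "))
    nm <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(nm))
        stop("duplicate set name(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    desc <- vapply(parts, `[[`, "", 2L)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- nm
    GeneSetLibrary(sets, desc)
}

#' @rdname readGmt
#' @param library a [GeneSetLibrary].
#' @export
writeGmt <- function(library, path) {
    stopifnot(methods::is(library, "GeneSetLibrary"))
    desc <- library@descriptions
    desc[!nzchar(desc)] <- "na"
    writeLines(vapply(seq_along(library@sets), function(i)
        paste(c(names(library@sets)[i], desc[i], library@sets[[i]]),
              collapse = "\t"), ""), path)
    invisible(path)
}
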