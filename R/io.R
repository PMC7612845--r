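## coerce any numeric matrix-like input to dgCMatrix
.asSparse <- function(x) {
  if (!is(x, "sparseMatrix")) x <- Matrix::Matrix(as.matrix(x) * 1.0, sparse = TRUE)
  as(as(x, "dMatrix"), "CsparseMatrix")
}

#' Read a sparse count matrix with gene and cell sidecars
#'
#' Reads a Matrix Market file of raw gene-by-cell counts together with its
#' `genes.tsv` and `cells.tsv` sidecars (tab-separated, header row; first
#' column `gene_id` / `cell_id`, any further cell columns are kept as
#' per-cell annotation). Genes are rows, cells are columns; sidecar order is
#' preserved.
#'
#' @param matrixPath Path to the `.mtx` file.
#' @param genesPath Path to the gene sidecar TSV.
#' @param cellsPath Path to the cell sidecar TSV.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (sparse, integral, nonnegative) and the cell annotations in
#'   `colData`.
#' @seealso [writeCounts()] for the exact inverse.
#' @export
readCounts <- function(matrixPath, genesPath, cellsPath) {
  for (p in c(matrixPath, genesPath, cellsPath))
    if (!file.exists(p)) .stopf("file not found: %s", p)
  m <- as(Matrix::readMM(matrixPath), "CsparseMatrix")
  genes <- read.delim(genesPath, header = TRUE, colClasses = "character")
  cells <- read.delim(cellsPath, header = TRUE, colClasses = NA)
  if (nrow(genes) != nrow(m))
    .stopf("dimension mismatch: %s declares %d genes but %s has %d rows",
           matrixPath, nrow(m), genesPath, nrow(genes))
  if (nrow(cells) != ncol(m))
    .stopf("dimension mismatch: %s declares %d cells but %s has %d rows",
           matrixPath, ncol(m), cellsPath, nrow(cells))
  geneIds <- genes[[1L]]
  cellIds <- as.character(cells[[1L]])
  if (anyDuplicated(geneIds))
    .stopf("duplicate gene ids in %s", genesPath)
  if (anyDuplicated(cellIds))
    .stopf("duplicate cell ids in %s", cellsPath)
  if (any(m@x < 0) || any(m@x != round(m@x)))
    .stopf("counts in %s must be nonnegative integers", matrixPath)
  dimnames(m) <- list(geneIds, cellIds)
  cd <- S4Vectors::DataFrame(cells[, -1L, drop = FALSE], row.names = cellIds)
  cd$cell_id <- cellIds
  SingleCellExperiment(assays = list(counts = m), colData = cd)
}

#' Write a count matrix as MTX plus TSV sidecars
#'
#' Inverse of [readCounts()]: writes `matrix.mtx`, `genes.tsv` and
#' `cells.tsv` into `outDir` so that reading them back reproduces the counts,
#' identifiers and order exactly.
#'
#' @param x A `SingleCellExperiment` with a `counts` assay, or a (sparse)
#'   matrix with dimnames.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
writeCounts <- function(x, outDir) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, "counts")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd <- cd[, setdiff(names(cd), "cell_id"), drop = FALSE]
  } else {
    m <- x
    cd <- data.frame(row.names = colnames(m))
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    .stopf("count matrix must have gene and cell names")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) .stopf("cannot create output directory %s", outDir)
  paths <- c(matrix = file.path(outDir, "matrix.mtx"),
             genes = file.path(outDir, "genes.tsv"),
             cells = file.path(outDir, "cells.tsv"))
  Matrix::writeMM(.asSparse(m), paths["matrix"])
  write.table(data.frame(gene_id = rownames(m)), paths["genes"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  cells <- data.frame(cell_id = colnames(m), cd, row.names = NULL,
                      check.names = FALSE)
  write.table(cells, paths["cells"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are dropped with a warning; a line with fewer than
#' three fields is a format error reported with its line number.
#'
#' @param path Path to the GMT file.
#' @return A named list of character gene vectors, with set descriptions in
#'   `attr(, "description")`.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      .stopf("GMT format error at line %d of %s: expected >= 3 tab-separated fields, got %d",
             i, path, length(fields))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      .warnf("GMT set '%s' (line %d): %d duplicate gene(s) dropped",
             fields[1L], i, sum(duplicated(genes)))
      genes <- unique(genes)
    }
    if (!length(genes))
      .stopf("GMT format error at line %d of %s: set '%s' is empty",
             i, path, fields[1L])
    sets[[fields[1L]]] <- genes
    desc[fields[1L]] <- fields[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions
#'   (default `"na"`).
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    .stopf("gene sets must be named")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[nm]))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Library-size normalize and log-transform counts
#'
#' Standard counts-per-`scaleFactor` normalization followed by natural
#' `log(1 + x)`: `value(g, c) = log1p(count(g, c) * scaleFactor / L_c)` with
#' `L_c` the cell's total counts. Cells with zero library size yield all-zero
#' columns and a warning. Zero counts map to zero exactly, so sparsity is
#' preserved.
#'
#' @param x A `SingleCellExperiment` with a `counts` assay, or a matrix of
#'   raw counts (genes x cells).
#' @param scaleFactor Target library size (default 10,000, the 10x
#'   convention).
#' @return For a `SingleCellExperiment` input, the object with a `logcounts`
#'   assay added; otherwise a sparse matrix of normalized values.
#' @export
logNormalizeCounts <- function(x, scaleFactor = 1e4) {
  if (!is.numeric(scaleFactor) || length(scaleFactor) != 1L || scaleFactor <= 0)
    .stopf("scaleFactor must be a single positive number")
  if (is(x, "SummarizedExperiment")) {
    ln <- logNormalizeCounts(SummarizedExperiment::assay(x, "counts"), scaleFactor)
    SummarizedExperiment::assay(x, "logcounts") <- ln
    return(x)
  }
  m <- .asSparse(x)
  if (any(m@x < 0)) .stopf("counts must be nonnegative")
  lib <- Matrix::colSums(m)
  if (any(lib == 0))
    .warnf("%d cell(s) with zero library size normalized to all-zero columns",
           sum(lib == 0))
  ncol <- ncol(m)
  colOf <- rep.int(seq_len(ncol), diff(m@p))
  m@x <- log1p(m@x * scaleFactor / lib[colOf])
  m
}
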