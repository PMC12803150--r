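# Plain-text readers/writers for the pipeline's standard formats: MTX plus
# barcodes/features TSV for count data, paired MTX for allele counts, CSV
# for tooth tables and result frames.

#' Write an AnnotatedCounts object as MTX + TSV + CSV
#'
#' Writes `matrix.mtx` (genes x cells), `barcodes.tsv`, `features.tsv`
#' (symbol and `mito` columns) and `cells.csv` (all cell annotations) into
#' `dir`.
#'
#' @param data an [AnnotatedCounts-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCountsDir <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMM(counts(data), file.path(dir, "matrix.mtx"))
  writeLines(colnames(data), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(symbol = rownames(data), mito = mitoGenes(data)),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(as.data.frame(colData(data)), file.path(dir, "cells.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read an AnnotatedCounts object written by [writeCountsDir()]
#'
#' @param dir directory holding `matrix.mtx`, `barcodes.tsv`, `features.tsv`
#'   and optionally `cells.csv`.
#' @return an [AnnotatedCounts-class].
#' @export
readCountsDir <- function(dir) {
  m <- as(readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  feat <- read.delim(file.path(dir, "features.tsv"))
  dimnames(m) <- list(feat$symbol, bcs)
  cellsFile <- file.path(dir, "cells.csv")
  cd <- if (file.exists(cellsFile)) read.csv(cellsFile) else NULL
  AnnotatedCounts(m, cellData = cd, mito = feat$mito)
}

#' Write allele-count data as paired MTX
#'
#' Writes `ref.mtx`, `alt.mtx`, `barcodes.tsv` and `variants.tsv`.
#'
#' @param data an [AlleleCountData-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeAlleleDir <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMM(refCounts(data), file.path(dir, "ref.mtx"))
  writeMM(altCounts(data), file.path(dir, "alt.mtx"))
  writeLines(rownames(refCounts(data)), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(refCounts(data)), file.path(dir, "variants.tsv"))
  invisible(dir)
}

#' Read allele-count data written by [writeAlleleDir()]
#'
#' @param dir directory holding the paired MTX files.
#' @return an [AlleleCountData-class].
#' @export
readAlleleDir <- function(dir) {
  ref <- as(readMM(file.path(dir, "ref.mtx")), "CsparseMatrix")
  alt <- as(readMM(file.path(dir, "alt.mtx")), "CsparseMatrix")
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  vars <- readLines(file.path(dir, "variants.tsv"))
  dimnames(ref) <- dimnames(alt) <- list(bcs, vars)
  AlleleCountData(ref, alt)
}

#' Read or write a tooth table CSV
#'
#' @param path CSV file path.
#' @return a `ToothTable` data.frame with logical dye columns.
#' @export
readToothTable <- function(path) {
  t <- read.csv(path)
  for (col in c("alizarin", "calcein")) t[[col]] <- as.logical(t[[col]])
  t
}

#' @rdname readToothTable
#' @param table a `ToothTable` data.frame.
#' @export
writeToothTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
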