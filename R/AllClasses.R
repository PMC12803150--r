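#' @include regenkit-package.R
NULL

# Cell annotation columns the pipeline understands. Any may be absent.
.CELL_ANNOTATIONS <- c("barcode", "cell_type", "condition", "timepoint",
                       "pool", "individual")

#' Annotated gene-by-cell count container
#'
#' `AnnotatedCounts` extends
#' [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#' with validity guarantees: a sparse non-negative integer `counts` assay, a
#' logical `mito` flag in `rowData`, and per-cell annotations (`cell_type`,
#' `condition`, `timepoint`, `pool`, `individual` -- any may be absent) whose
#' lengths match the matrix. It is the substrate of every pipeline stage.
#'
#' @slot .. inherits all slots from `SingleCellExperiment`.
#' @export
setClass("AnnotatedCounts", contains = "SingleCellExperiment")

setValidity("AnnotatedCounts", function(object) {
  msg <- NULL
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (length(m) && min(m) < 0) msg <- c(msg, "counts must be non-negative")
  }
  if (!"mito" %in% names(rowData(object)))
    msg <- c(msg, "rowData must contain a logical 'mito' flag")
  else if (!is.logical(rowData(object)$mito))
    msg <- c(msg, "'mito' flag must be logical")
  if (is.null(colnames(object)))
    msg <- c(msg, "cells must carry barcode names (colnames)")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AnnotatedCounts object
#'
#' @param counts sparse (or dense, coerced) non-negative integer matrix,
#'   genes x cells. Dimnames are used as gene symbols and barcodes.
#' @param cellData data.frame of per-cell annotations (columns among
#'   `cell_type`, `condition`, `timepoint`, `pool`, `individual`).
#' @param mito logical per-gene mitochondrial flag; defaults to all `FALSE`.
#' @return an [AnnotatedCounts-class] object.
#' @examples
#' m <- Matrix::rsparsematrix(20, 5, 0.3, rand.x = function(n) rpois(n, 2) + 1)
#' dimnames(m) <- list(paste0("g", 1:20), paste0("bc", 1:5))
#' ac <- AnnotatedCounts(abs(m))
#' @export
AnnotatedCounts <- function(counts, cellData = NULL, mito = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell_", seq_len(ncol(counts)))
  if (is.null(mito)) mito <- rep(FALSE, nrow(counts))
  rd <- DataFrame(symbol = rownames(counts), mito = as.logical(mito))
  cd <- DataFrame(barcode = colnames(counts), row.names = colnames(counts))
  if (!is.null(cellData)) {
    stopifnot(nrow(cellData) == ncol(counts))
    for (col in setdiff(colnames(cellData), "barcode"))
      cd[[col]] <- cellData[[col]]
  }
  sce <- SingleCellExperiment(assays = list(counts = counts),
                              rowData = rd, colData = cd)
  new("AnnotatedCounts", sce)
}

#' @describeIn AnnotatedCounts logical mitochondrial flag per gene.
#' @param x an `AnnotatedCounts` object.
#' @export
mitoGenes <- function(x) rowData(x)$mito

#' @describeIn AnnotatedCounts per-cell type labels (or NULL).
#' @export
cellTypes <- function(x) colData(x)$cell_type

setMethod("show", "AnnotatedCounts", function(object) {
  cat("AnnotatedCounts:", nrow(object), "genes x", ncol(object), "cells\n")
  ann <- intersect(.CELL_ANNOTATIONS, colnames(colData(object)))
  cat("  annotations:", paste(ann, collapse = ", "), "\n")
  cat("  mito genes:", sum(rowData(object)$mito), "\n")
  invisible(NULL)
})

#' Per-nucleus allele counts at shared variants
#'
#' Paired sparse non-negative integer matrices of reference and alternate
#' allele counts (nuclei x variants), the evidence for pooled-genotype
#' deconvolution. A variant with zero coverage in a nucleus is simply absent
#' from both matrices.
#'
#' @slot refCounts,altCounts sparse nuclei x variants count matrices,
#'   congruent in dimension and dimnames.
#' @export
setClass("AlleleCountData",
         representation(refCounts = "dgCMatrix", altCounts = "dgCMatrix"))

setValidity("AlleleCountData", function(object) {
  msg <- NULL
  if (!identical(dim(object@refCounts), dim(object@altCounts)))
    msg <- c(msg, "ref and alt matrices must be congruent")
  if (length(object@refCounts@x) && min(object@refCounts@x) < 0)
    msg <- c(msg, "negative ref counts")
  if (length(object@altCounts@x) && min(object@altCounts@x) < 0)
    msg <- c(msg, "negative alt counts")
  if (is.null(msg)) TRUE else msg
})

#' Construct AlleleCountData
#' @param refCounts,altCounts nuclei x variants sparse count matrices.
#' @return an [AlleleCountData-class] object.
#' @export
AlleleCountData <- function(refCounts, altCounts) {
  refCounts <- as(as(refCounts, "CsparseMatrix"), "dMatrix")
  altCounts <- as(as(altCounts, "CsparseMatrix"), "dMatrix")
  if (!identical(dim(refCounts), dim(altCounts)))
    stop("ref and alt matrices must be congruent")
  if (is.null(rownames(refCounts)))
    rownames(refCounts) <- paste0("nuc_", seq_len(nrow(refCounts)))
  if (is.null(colnames(refCounts)))
    colnames(refCounts) <- paste0("var_", seq_len(ncol(refCounts)))
  dimnames(altCounts) <- dimnames(refCounts)
  new("AlleleCountData", refCounts = refCounts, altCounts = altCounts)
}

#' @describeIn AlleleCountData reference-allele count matrix.
#' @param x an `AlleleCountData` object.
#' @export
refCounts <- function(x) x@refCounts

#' @describeIn AlleleCountData alternate-allele count matrix.
#' @export
altCounts <- function(x) x@altCounts

#' @describeIn AlleleCountData nucleus barcodes.
#' @export
nucleusBarcodes <- function(x) rownames(x@refCounts)

setMethod("show", "AlleleCountData", function(object) {
  cat("AlleleCountData:", nrow(object@refCounts), "nuclei x",
      ncol(object@refCounts), "variants\n")
  cat("  mean depth/variant:",
      signif(mean(object@refCounts + object@altCounts), 3), "\n")
  invisible(NULL)
})

#' Genotype assignment of pooled nuclei
#'
#' Per-nucleus label (`"1"`..`"K"`, `"doublet"` or `"unassigned"`), posterior
#' probability of the winning hypothesis, and the full log-likelihood matrix
#' over singlet and doublet hypotheses.
#'
#' @slot barcode character nucleus barcodes.
#' @slot label character assignment per nucleus.
#' @slot posterior numeric posterior of the winning hypothesis, in `[0, 1]`.
#' @slot logLik matrix of per-hypothesis log-likelihoods (nuclei x hypotheses).
#' @slot k integer number of genotype clusters.
#' @slot logLikTrace numeric EM total log-likelihood per iteration (best restart).
#' @export
setClass("GenotypeAssignment",
         representation(barcode = "character", label = "character",
                        posterior = "numeric", logLik = "matrix",
                        k = "integer", logLikTrace = "numeric"))

setValidity("GenotypeAssignment", function(object) {
  msg <- NULL
  n <- length(object@barcode)
  if (length(object@label) != n || length(object@posterior) != n)
    msg <- c(msg, "barcode/label/posterior lengths differ")
  ok <- !is.na(object@posterior)
  if (any(object@posterior[ok] < -1e-9 | object@posterior[ok] > 1 + 1e-9))
    msg <- c(msg, "posteriors outside [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn GenotypeAssignment assignment labels per nucleus.
#' @param x a `GenotypeAssignment` object.
#' @export
assignmentLabels <- function(x) setNames(x@label, x@barcode)

#' @describeIn GenotypeAssignment posterior of the winning hypothesis.
#' @export
assignmentPosteriors <- function(x) setNames(x@posterior, x@barcode)

setMethod("show", "GenotypeAssignment", function(object) {
  cat("GenotypeAssignment: k =", object@k, ",", length(object@barcode),
      "nuclei\n")
  print(table(object@label))
  invisible(NULL)
})

#' Cross-species cell-type similarity result
#'
#' Similarity score matrix `S` over (type in A, type in B) pairs, the
#' permutation null used to flag significant pairs, and empirical p-values.
#' `S(a, b)` is the average number of type-`a` cells of dataset A among the
#' k cross-dataset nearest neighbors of dataset-B cells of type `b`.
#'
#' @slot scores numeric matrix, rows = types of A, columns = types of B.
#' @slot pValues empirical permutation p-values, `(1 + #{perm >= obs})/(n+1)`.
#' @slot significant logical; observed strictly exceeds every permuted score.
#' @slot k integer neighbors used.
#' @slot nPerm integer permutations.
#' @slot direction `"BtoA"` or `"symmetric"`.
#' @slot null `"pair"` or `"rowmax"` exceedance rule.
#' @export
setClass("SimilarityResult",
         representation(scores = "matrix", pValues = "matrix",
                        significant = "matrix", k = "integer",
                        nPerm = "integer", direction = "character",
                        null = "character"))

setValidity("SimilarityResult", function(object) {
  msg <- NULL
  if (!identical(dim(object@scores), dim(object@pValues)) ||
      !identical(dim(object@scores), dim(object@significant)))
    msg <- c(msg, "scores/pValues/significant dimensions differ")
  s <- object@scores[!is.na(object@scores)]
  if (length(s) && (min(s) < 0 || max(s) > object@k + 1e-9))
    msg <- c(msg, "scores must lie in [0, k]")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SimilarityResult the similarity score matrix.
#' @param x a `SimilarityResult` object.
#' @export
similarityMatrix <- function(x) x@scores

#' @describeIn SimilarityResult logical significance flags.
#' @export
significantPairs <- function(x) x@significant

setMethod("show", "SimilarityResult", function(object) {
  cat("SimilarityResult:", nrow(object@scores), "x", ncol(object@scores),
      "type pairs, k =", object@k, ", nPerm =", object@nPerm,
      ", null =", object@null, "\n")
  cat("  significant pairs:", sum(object@significant, na.rm = TRUE), "\n")
  invisible(NULL)
})

#' Cell-cell communication network
#'
#' Probability tensor `P` over (sender type, receiver type, interaction) with
#' label-permutation p-values. Probabilities are mass-action/Hill saturated
#' and masked to zero where not significant before any aggregation.
#'
#' @slot prob 3-d array sender x receiver x interaction, entries in `[0, 1)`.
#' @slot rawProb the unmasked probabilities.
#' @slot pValues permutation p-values, same shape.
#' @slot pathways character pathway per interaction.
#' @slot params list (Kh, trim, nPerm, alpha, seed).
#' @export
setClass("CommunicationNetwork",
         representation(prob = "array", rawProb = "array", pValues = "array",
                        pathways = "character", params = "list"))

setValidity("CommunicationNetwork", function(object) {
  msg <- NULL
  p <- object@prob
  if (length(dim(p)) != 3) msg <- c(msg, "prob must be a 3-d array")
  if (length(p) && (min(p) < 0 || max(p) >= 1))
    msg <- c(msg, "probabilities must lie in [0, 1)")
  if (length(object@pathways) != dim(p)[3])
    msg <- c(msg, "one pathway per interaction required")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn CommunicationNetwork significance-masked probability tensor.
#' @param x a `CommunicationNetwork` object.
#' @export
commProb <- function(x) x@prob

#' @describeIn CommunicationNetwork cell-type alphabet of the network.
#' @export
commTypes <- function(x) dimnames(x@prob)[[1]]

setMethod("show", "CommunicationNetwork", function(object) {
  d <- dim(object@prob)
  cat("CommunicationNetwork:", d[1], "senders x", d[2], "receivers x", d[3],
      "interactions\n")
  cat("  significant entries:", sum(object@prob > 0), "; pathways:",
      length(unique(object@pathways)), "\n")
  invisible(NULL)
})
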