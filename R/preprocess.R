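# Barcode QC, normalization, HVG selection, PCA, kNN graph: the shared
# substrate for the homology, potential and communication stages.

#' Filter barcodes on detected genes and mitochondrial fraction
#'
#' Retains barcodes with `minGenes <= genes detected <= maxGenes` and
#' mitochondrial count fraction `<= maxMito`. "Genes detected" means genes
#' with count > 0; the mitochondrial fraction is computed on raw counts. The
#' bounds are inclusive on the retained side: a barcode at exactly 2,500
#' detected genes or exactly 5% mitochondrial reads is kept.
#'
#' @param data an [AnnotatedCounts-class]; must carry the `mito` flag.
#' @param minGenes,maxGenes inclusive bounds on genes detected.
#' @param maxMito inclusive upper bound on the mitochondrial fraction.
#' @return the filtered [AnnotatedCounts-class], cell order preserved; the
#'   per-barcode decision log is in `metadata()$qc` (barcode, genes,
#'   mito_frac, kept, reason).
#' @export
filterBarcodes <- function(data, minGenes = 250, maxGenes = 2500,
                           maxMito = 0.05) {
  stopifnot(is(data, "AnnotatedCounts"))
  mito <- mitoGenes(data)
  if (is.null(mito)) stop("mito flags are required for barcode QC")
  m <- counts(data)
  genes <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  mitoFrac <- ifelse(total == 0, 0,
                     Matrix::colSums(m[mito, , drop = FALSE]) / total)
  reason <- rep("", ncol(m))
  reason[genes < minGenes] <- "low_genes"
  reason[genes > maxGenes] <- paste0(reason[genes > maxGenes], ";high_genes")
  reason[mitoFrac > maxMito] <- paste0(reason[mitoFrac > maxMito], ";high_mito")
  reason <- sub("^;", "", reason)
  kept <- reason == ""
  qc <- data.frame(barcode = colnames(m), genes = as.integer(genes),
                   mito_frac = as.numeric(mitoFrac), kept = kept,
                   reason = ifelse(kept, "pass", reason))
  out <- data[, kept]
  metadata(out)$qc <- qc
  out
}

#' Log-normalize counts
#'
#' `log(1 + count / cellTotal * scaleFactor)`, natural log. Adds a
#' `logcounts` assay when given an [AnnotatedCounts-class]; returns the
#' normalized matrix when given a bare matrix.
#'
#' @param data an [AnnotatedCounts-class] or a genes x cells count matrix.
#' @param scaleFactor counts-per-scale constant (default 10,000).
#' @return same class as the input (with `logcounts` filled) or a matrix.
#' @export
logNormalize <- function(data, scaleFactor = 1e4) {
  m <- if (is(data, "AnnotatedCounts")) counts(data) else data
  if (!is(m, "CsparseMatrix")) m <- as(as(m, "CsparseMatrix"), "dMatrix")
  total <- Matrix::colSums(m)
  if (any(total == 0)) {
    bad <- colnames(m)[total == 0]
    stop("cells with zero total counts: ", paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  norm <- m %*% Diagonal(x = scaleFactor / total)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  if (is(data, "AnnotatedCounts")) {
    logcounts(data) <- norm
    metadata(data)$scaleFactor <- scaleFactor
    data
  } else norm
}

#' Select highly variable genes by binned dispersion
#'
#' Mean/variability selection in the mean.var.plot mold: genes are binned
#' into `nBins` equal-frequency bins of mean normalized expression, the
#' dispersion (variance/mean of the normalized values) is z-scored within
#' each bin, and the top `n` genes by standardized dispersion are returned.
#' Constant genes are never selected; ties break by gene order.
#'
#' @param norm an [AnnotatedCounts-class] with `logcounts`, or a normalized
#'   genes x cells matrix.
#' @param n number of genes to return.
#' @param nBins equal-frequency mean bins.
#' @return character vector of selected gene names (or indices when the
#'   matrix has no rownames), ordered by decreasing standardized dispersion.
#' @export
selectHVG <- function(norm, n = 4000, nBins = 20) {
  stopifnot(n > 0)
  m <- .asDense(.normMatrix(norm))
  stopifnot(n <= nrow(m))
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  usable <- which(v > 0)
  nb <- max(1L, min(nBins, length(usable)))
  bins <- cut(rank(mu[usable], ties.method = "first"),
              breaks = nb, labels = FALSE)
  zdisp <- rep(-Inf, nrow(m))
  for (b in unique(bins)) {
    idx <- usable[bins == b]
    d <- disp[idx]
    s <- sd(d)
    zdisp_b <- if (is.na(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
    zdisp[idx] <- zdisp_b
  }
  ord <- order(-zdisp, seq_len(nrow(m)))
  sel <- ord[seq_len(min(n, length(usable)))]
  sel <- sel[zdisp[sel] > -Inf]
  if (!is.null(rownames(m))) rownames(m)[sel] else sel
}

#' PCA embedding of normalized expression
#'
#' Centers genes and projects cells onto the leading principal components.
#' The sign of each component is fixed so its largest-magnitude gene loading
#' is positive, making the embedding reproducible.
#'
#' @param norm an [AnnotatedCounts-class] with `logcounts`, or a normalized
#'   genes x cells matrix.
#' @param genes gene subset to use (default all).
#' @param nComponents dimensions to keep (<= min(genes, cells)).
#' @return an `Embedding`: list with `coordinates` (cells x d),
#'   `varExplained` (variance per component, non-increasing), `rotation`.
#' @export
embedPCA <- function(norm, genes = NULL, nComponents = 50) {
  m <- .asDense(.normMatrix(norm))
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  stopifnot(nComponents >= 1)
  if (all(apply(m, 1, var) == 0)) stop("all genes constant: nothing to embed")
  x <- Matrix::t(m)                       # cells x genes
  nComponents <- min(nComponents, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = nComponents)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, "*")
  rot <- sweep(pc$rotation, 2, flip, "*")
  rownames(coords) <- colnames(m)
  structure(list(coordinates = coords,
                 varExplained = pc$sdev[seq_len(ncol(coords))]^2,
                 rotation = rot),
            class = "Embedding")
}

#' Exact k-nearest-neighbor graph
#'
#' Euclidean k nearest neighbors per cell, self excluded, ties broken by cell
#' index. If fewer than `k + 1` cells exist, `k` is clamped to `n - 1`.
#'
#' @param emb an `Embedding` from [embedPCA()], or a cells x d coordinate
#'   matrix.
#' @param k neighbors per cell.
#' @return a `KnnGraph`: list with `index` and `dist` (both n x k) and `k`.
#' @export
buildKNN <- function(emb, k = 50) {
  stopifnot(k > 0)
  x <- if (inherits(emb, "Embedding")) emb$coordinates else as.matrix(emb)
  n <- nrow(x)
  if (k > n - 1L) {
    warning("k clamped to n - 1 = ", n - 1L)
    k <- n - 1L
  }
  res <- .knnSearch(x, x, k, exclude = seq_len(n))
  structure(list(index = res$index, dist = res$dist, k = as.integer(k),
                 n = n, barcodes = rownames(x)),
            class = "KnnGraph")
}

# Sparse n x n adjacency (directed, i -> its k neighbors) of a KnnGraph.
.knnAdjacency <- function(graph) {
  n <- graph$n; k <- graph$k
  sparseMatrix(i = rep(seq_len(n), each = k),
               j = as.vector(Matrix::t(graph$index)),
               x = 1, dims = c(n, n))
}
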