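# Internal numerical helpers shared across modules.

# Rank-scale a vector to [0, 1]; ties get their average rank, so a constant
# vector maps to 0.5 everywhere and a non-constant vector spans [0, 1].
.rankScale <- function(x) {
  n <- length(x)
  if (n == 1L) return(0.5)
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

# Dense numeric matrix from whatever container a stage hands us.
.asDense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

# Extract the log-normalized genes x cells matrix from an AnnotatedCounts
# (requires logNormalize() to have been run) or pass a plain matrix through.
.normMatrix <- function(x) {
  if (is(x, "AnnotatedCounts")) {
    if (!"logcounts" %in% names(assays(x)))
      stop("no 'logcounts' assay: run logNormalize() first")
    assay(x, "logcounts")
  } else x
}

# Vectorized two-sample Wilcoxon rank-sum over the rows of a matrix.
# Normal approximation with tie correction, no continuity correction.
# Returns a data.frame with the standardized statistic and p-values for
# both sidedness conventions. `group1` is a logical selector over columns.
.rankSumRows <- function(mat, group1) {
  mat <- .asDense(mat)
  n <- ncol(mat)
  n1 <- sum(group1)
  n2 <- n - n1
  stopifnot(n1 > 0, n2 > 0)
  ranks <- t(apply(mat, 1L, rank, ties.method = "average"))
  if (nrow(mat) == 1L) ranks <- matrix(ranks, nrow = 1L)
  r1 <- rowSums(ranks[, group1, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2           # Mann-Whitney U for group 1
  mu <- n1 * n2 / 2
  # tie correction: sum over tie groups of (t^3 - t), per gene
  tieTerm <- apply(mat, 1L, function(x) {
    t <- table(x); sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tieTerm / (n * (n - 1)))
  z <- ifelse(sigma2 > 0, (u - mu) / sqrt(sigma2), 0)
  data.frame(statistic = u,
             z = z,
             p.two.sided = ifelse(sigma2 > 0, 2 * pnorm(-abs(z)), 1),
             p.greater = ifelse(sigma2 > 0, pnorm(-z), 1),
             row.names = rownames(mat))
}

# log2 fold change between two cell groups on log-normalized data, the
# convention of mainstream scRNA-seq toolkits: means are taken on the
# de-logged (counts-per-scale) values, with a +1 regularizer.
.log2FC <- function(norm, group1) {
  norm <- .asDense(norm)
  m1 <- rowMeans(expm1(norm[, group1, drop = FALSE]))
  m2 <- rowMeans(expm1(norm[, !group1, drop = FALSE]))
  log2((m1 + 1) / (m2 + 1))
}

# Fraction of cells with detectable (> 0) expression per gene, by group.
.pctExpressed <- function(norm, cells) {
  Matrix::rowSums(norm[, cells, drop = FALSE] > 0) / max(1L, sum(cells))
}

# Exact k-nearest-neighbor search between the rows of `query` and `ref`
# (Euclidean). Ties broken by reference row index; `exclude` optionally maps
# each query row to one reference row to skip (self-matching). Blockwise to
# bound memory. Returns list(index, dist), each n_query x k.
.knnSearch <- function(query, ref, k, exclude = NULL, block = 512L) {
  nq <- nrow(query); nr <- nrow(ref)
  stopifnot(k >= 1L, k <= nr - as.integer(!is.null(exclude) && nr == nq))
  idx <- matrix(NA_integer_, nq, k)
  dst <- matrix(NA_real_, nq, k)
  refSq <- rowSums(ref^2)
  for (start in seq(1L, nq, by = block)) {
    rows <- start:min(start + block - 1L, nq)
    q <- query[rows, , drop = FALSE]
    # squared distances, clamped at 0 for numerical safety
    d2 <- outer(rowSums(q^2), refSq, "+") - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    for (i in seq_along(rows)) {
      d <- d2[i, ]
      if (!is.null(exclude)) d[exclude[rows[i]]] <- Inf
      ord <- order(d, seq_len(nr))[seq_len(k)]
      idx[rows[i], ] <- ord
      dst[rows[i], ] <- sqrt(d[ord])
    }
  }
  list(index = idx, dist = dst)
}

# Row-normalize a sparse non-negative matrix; all-zero rows get a self-loop.
.rowStochastic <- function(m) {
  rs <- Matrix::rowSums(m)
  zero <- which(rs == 0)
  if (length(zero))
    m <- m + sparseMatrix(i = zero, j = zero, x = 1, dims = dim(m))
  rs <- Matrix::rowSums(m)
  Diagonal(x = 1 / rs) %*% m
}

.checkSeed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer(seed)
}
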