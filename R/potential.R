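# Developmental-potential scores from transcriptional diversity, directed
# transition kernels on the kNN graph, vector-field projection, and the
# Moran's I trajectory-gene test.

#' Gene-count developmental-potential scores
#'
#' Uses the transcriptional-diversity assumption: naive cells express more
#' genes than mature cells. The detected-gene count per cell is rank-scaled
#' to `[0, 1]`, smoothed by `m` rounds of graph diffusion
#' `c <- (1 - alpha) * g + alpha * A c` with the row-normalized kNN
#' adjacency `A`, and finally rank-scaled again, so scores are ordinal: 1 =
#' most naive, 0 = most mature, ties share their mid-rank value.
#'
#' @param data an [AnnotatedCounts-class] (raw counts are used).
#' @param graph a `KnnGraph` over the same cells.
#' @param alpha diffusion weight in `[0, 1)`.
#' @param m smoothing iterations.
#' @return list with `score` (per-cell, in `[0, 1]`), `geneCount` (raw g),
#'   `alpha`, `m`.
#' @export
potentialScores <- function(data, graph, alpha = 0.5, m = 3) {
  stopifnot(inherits(graph, "KnnGraph"), alpha >= 0, alpha < 1, m >= 0)
  cnt <- counts(data)
  n <- ncol(cnt)
  if (graph$n != n) stop("graph and data cover different cells")
  if (n == 0) stop("empty graph")
  g <- as.numeric(Matrix::colSums(cnt > 0))
  A <- .rowStochastic(.knnAdjacency(graph))
  s <- .rankScale(g)
  for (i in seq_len(m)) s <- (1 - alpha) * .rankScale(g) + alpha *
      as.numeric(A %*% s)
  score <- .rankScale(s)
  # min-max rescale so a non-constant score always spans [0, 1] even with
  # ties at the extremes (tied cells keep a common value)
  rng <- range(score)
  if (rng[2] > rng[1]) score <- (score - rng[1]) / (rng[2] - rng[1])
  list(score = setNames(score, colnames(cnt)),
       geneCount = setNames(g, colnames(cnt)), alpha = alpha, m = m)
}

#' Directed transition matrix biased by developmental potential
#'
#' For each kNN edge i -> j, the transition probability is proportional to
#' `exp(beta * (t_j - t_i))` with differentiation pseudotime `t = 1 - score`,
#' row-normalized. `beta = 0` recovers the unbiased row-normalized graph;
#' larger `beta` concentrates transitions on neighbors later in pseudotime.
#' Isolated rows receive a self-loop.
#'
#' @param graph a `KnnGraph`.
#' @param scores output of [potentialScores()] or a numeric score vector.
#' @param beta directional bias (>= 0 points "forward" in differentiation).
#' @return a sparse row-stochastic `dgCMatrix` with attributes `beta` and
#'   `pseudotime`.
#' @export
transitionMatrix <- function(graph, scores, beta = 10) {
  s <- if (is.list(scores)) scores$score else scores
  stopifnot(inherits(graph, "KnnGraph"), length(s) == graph$n)
  t <- 1 - s
  n <- graph$n; k <- graph$k
  i <- rep(seq_len(n), each = k)
  j <- as.vector(Matrix::t(graph$index))
  w <- exp(beta * (t[j] - t[i]))
  # normalize within rows; exp is bounded here because |dt| <= 1
  T <- sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  T <- .rowStochastic(T)
  T <- as(T, "CsparseMatrix")
  dimnames(T) <- list(graph$barcodes, graph$barcodes)
  attr(T, "beta") <- beta
  attr(T, "pseudotime") <- t
  T
}

#' Project a transition matrix as a vector field
#'
#' The displacement arrow of cell i is the expected embedding step
#' `sum_j T_ij (x_j - x_i)`.
#'
#' @param T row-stochastic transition matrix from [transitionMatrix()].
#' @param emb an `Embedding` (or coordinate matrix) over the same cells.
#' @return cells x d matrix of displacement vectors.
#' @export
projectField <- function(T, emb) {
  x <- if (inherits(emb, "Embedding")) emb$coordinates else as.matrix(emb)
  stopifnot(nrow(x) == nrow(T))
  as.matrix(T %*% x) - x
}

#' Moran's I autocorrelation test per gene on the cell graph
#'
#' Computes `I = (n/W) * (sum_ij w_ij z_i z_j) / (sum_i z_i^2)` per gene on
#' the symmetrized binary kNN adjacency, with `z` the centered expression.
#' Significance is the analytic normal approximation against
#' `E[I] = -1/(n-1)` (one-sided, positive autocorrelation), BH-adjusted.
#' Constant genes are flagged and excluded from testing.
#'
#' @param norm an [AnnotatedCounts-class] with `logcounts`, or a normalized
#'   genes x cells matrix.
#' @param graph a `KnnGraph` over the cells, or a symmetric non-negative
#'   weight matrix.
#' @return data.frame with columns gene, moranI, z, p, q, constant.
#' @export
moranTest <- function(norm, graph) {
  m <- .asDense(.normMatrix(norm))
  W <- if (inherits(graph, "KnnGraph")) {
    A <- .knnAdjacency(graph)
    A <- as(A + Matrix::t(A), "CsparseMatrix")
    A@x <- pmin(A@x, 1)              # symmetrized binary weights
    A
  } else as(graph, "CsparseMatrix")
  if (length(W@x) && min(W@x) < 0) stop("graph weights must be non-negative")
  n <- ncol(m)
  stopifnot(nrow(W) == n)
  Wtot <- sum(W)
  Z <- m - rowMeans(m)
  num <- rowSums(as.matrix(Z %*% W) * Z)
  den <- rowSums(Z^2)
  constant <- den == 0
  I <- ifelse(constant, NA_real_, (n / Wtot) * num / den)
  # normality-assumption moments for symmetric weights
  EI <- -1 / (n - 1)
  S1 <- sum((W + Matrix::t(W))^2) / 2
  deg <- Matrix::rowSums(W) + Matrix::colSums(W)
  S2 <- sum(deg^2)
  varI <- (n^2 * S1 - n * S2 + 3 * Wtot^2) / (Wtot^2 * (n^2 - 1)) - EI^2
  z <- (I - EI) / sqrt(varI)
  p <- pnorm(z, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[!constant] <- p.adjust(p[!constant], method = "BH")
  data.frame(gene = rownames(m) %||% as.character(seq_len(nrow(m))),
             moranI = I, z = z, p = p, q = q, constant = constant,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select trajectory-variable genes
#'
#' Genes passing `q < qMax`, then the `topN` with the highest Moran's I.
#'
#' @param res data.frame from [moranTest()].
#' @param qMax q-value threshold (strict `<`).
#' @param topN maximum genes returned, ranked by decreasing I.
#' @return character vector of gene names sorted by decreasing Moran's I.
#' @export
selectTrajectoryGenes <- function(res, qMax = 0.01, topN = 300) {
  pass <- res[!res$constant & !is.na(res$q) & res$q < qMax, , drop = FALSE]
  pass <- pass[order(-pass$moranI, pass$gene), , drop = FALSE]
  head(pass$gene, topN)
}

#' Compare developmental potential between conditions per cell type
#'
#' Median potential-score difference (plucked minus control) and a two-sided
#' rank-sum p per cell type, BH-adjusted across types. Types observed in only
#' one condition are skipped with a warning.
#'
#' @param scores numeric per-cell potential scores.
#' @param condition per-cell condition labels (two levels; `"plucked"` taken
#'   as the focal level if present, else the second level).
#' @param cellType per-cell type labels.
#' @return data.frame with cell_type, medianDiff, p, q, n1, n2.
#' @export
comparePotential <- function(scores, condition, cellType) {
  stopifnot(length(scores) == length(condition),
            length(scores) == length(cellType))
  condition <- as.character(condition)
  lv <- unique(condition)
  stopifnot(length(lv) == 2)
  focal <- if ("plucked" %in% lv) "plucked" else lv[2]
  out <- list(); skipped <- character(0)
  for (ct in unique(cellType)) {
    sel <- cellType == ct
    x <- scores[sel & condition == focal]
    y <- scores[sel & condition != focal]
    if (length(x) == 0 || length(y) == 0) {
      skipped <- c(skipped, ct)
      next
    }
    p <- .rankSumRows(matrix(c(x, y), nrow = 1),
                      c(rep(TRUE, length(x)), rep(FALSE, length(y))))
    out[[ct]] <- data.frame(cell_type = ct,
                            medianDiff = median(x) - median(y),
                            p = p$p.two.sided, n1 = length(x),
                            n2 = length(y))
  }
  if (length(skipped))
    warning("types with a single condition skipped: ",
            paste(skipped, collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame())
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
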