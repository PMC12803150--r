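# Cross-species cell-type similarity: homology-weighted joint embedding,
# cross-dataset kNN, the average-neighbor-count similarity score, and the
# strict permutation significance rule.

#' Jointly embed two species on a weighted homology table
#'
#' Expression of dataset B is projected into A's gene space through the
#' homology mapping: each A gene becomes the weight-normalized mean of its B
#' partners, so genes with higher homology weight influence the integration
#' more, and uniform weight rescaling cancels. The concatenated matrices are
#' then jointly log-normalized and PCA-embedded.
#'
#' @param dataA,dataB [AnnotatedCounts-class] objects.
#' @param table data.frame with columns `geneA`, `geneB`, `weight` in (0, 1].
#'   Rows naming genes absent from either dataset are dropped with a warning.
#' @param nComponents PCA dimensions.
#' @param scaleFactor joint log-normalization scale.
#' @return an `Embedding` over all cells of A then B, with attributes
#'   `dataset` (factor "A"/"B") and `barcodes`.
#' @export
jointEmbed <- function(dataA, dataB, table, nComponents = 50,
                       scaleFactor = 1e4) {
  stopifnot(all(c("geneA", "geneB", "weight") %in% colnames(table)))
  if (any(table$weight <= 0)) stop("homology weights must be positive")
  ok <- table$geneA %in% rownames(dataA) & table$geneB %in% rownames(dataB)
  if (!all(ok))
    warning(sum(!ok), " homology rows dropped (genes absent)")
  table <- table[ok, , drop = FALSE]
  if (nrow(table) == 0) stop("no usable homolog pairs")
  if (nrow(table) < 20)
    stop("fewer than 20 usable homolog pairs: ", nrow(table))
  genesA <- unique(table$geneA)
  cntA <- counts(dataA)[genesA, , drop = FALSE]
  # sparse projection operator: A genes x B genes, rows weight-normalized
  iA <- match(table$geneA, genesA)
  iB <- match(table$geneB, rownames(dataB))
  proj <- sparseMatrix(i = iA, j = iB, x = table$weight,
                       dims = c(length(genesA), nrow(dataB)))
  proj <- Diagonal(x = 1 / Matrix::rowSums(proj)) %*% proj
  cntB <- proj %*% counts(dataB)
  joint <- cbind(cntA, cntB)
  colnames(joint) <- c(paste0("A|", colnames(dataA)),
                       paste0("B|", colnames(dataB)))
  norm <- logNormalize(joint, scaleFactor = scaleFactor)
  emb <- embedPCA(norm, nComponents = nComponents)
  attr(emb, "dataset") <- factor(rep(c("A", "B"),
                                     c(ncol(dataA), ncol(dataB))))
  attr(emb, "barcodes") <- c(colnames(dataA), colnames(dataB))
  emb
}

#' Cross-dataset k-nearest neighbors
#'
#' For every cell, its `k` exact Euclidean nearest neighbors restricted to
#' the other dataset.
#'
#' @param embedding a tagged `Embedding` from [jointEmbed()], or a coordinate
#'   matrix plus a `dataset` factor.
#' @param k neighbors; must be `<=` the size of the opposite dataset.
#' @param dataset optional two-level factor when `embedding` is a bare matrix.
#' @return list with `indexA` (nA x k, indices into B cells), `distA`,
#'   `indexB`, `distB`, and `k`.
#' @export
crossKNN <- function(embedding, k = 50, dataset = NULL) {
  stopifnot(k > 0)
  x <- if (inherits(embedding, "Embedding")) embedding$coordinates
       else as.matrix(embedding)
  ds <- if (is.null(dataset)) attr(embedding, "dataset") else factor(dataset)
  stopifnot(!is.null(ds), nlevels(ds) == 2, length(ds) == nrow(x))
  a <- ds == levels(ds)[1]
  xA <- x[a, , drop = FALSE]; xB <- x[!a, , drop = FALSE]
  if (k > nrow(xA) || k > nrow(xB))
    stop("k exceeds the size of the opposite dataset")
  resA <- .knnSearch(xA, xB, k)
  resB <- .knnSearch(xB, xA, k)
  list(indexA = resA$index, distA = resA$dist,
       indexB = resB$index, distB = resB$dist, k = as.integer(k))
}

# Score matrix from neighbor counts. Direction "BtoA": S(a, b) = mean over
# B cells of type b of the number of type-a A cells among their k neighbors.
.scoreMatrix <- function(indexB, labelsA, labelsB, typesA, typesB) {
  labA <- factor(labelsA, levels = typesA)
  labB <- factor(labelsB, levels = typesB)
  nB <- length(labB)
  # neighbor labels of each B cell, tabulated per type of A
  neighLab <- matrix(as.integer(labA[indexB]), nrow = nB)
  S <- matrix(0, length(typesA), length(typesB),
              dimnames = list(typesA, typesB))
  cnt <- matrix(0L, nB, length(typesA))
  for (a in seq_along(typesA))
    cnt[, a] <- rowSums(neighLab == a, na.rm = TRUE)
  for (b in seq_along(typesB)) {
    cells <- which(as.integer(labB) == b)
    S[, b] <- if (length(cells)) colMeans(cnt[cells, , drop = FALSE])
              else NA_real_
  }
  S
}

#' Cross-species cell-type similarity scores
#'
#' `S(a, b)` is the average, over dataset-B cells of type `b`, of the number
#' of type-`a` dataset-A cells among their `k` cross-dataset nearest
#' neighbors (direction B to A). With `direction = "symmetric"` the mean of
#' the two directed scores is returned. Types with no cells score `NA`.
#'
#' @param graph a cross-dataset kNN structure from [crossKNN()].
#' @param labelsA,labelsB cell-type labels for the A and B cells.
#' @param direction `"BtoA"` (default) or `"symmetric"`.
#' @return numeric matrix, rows = A types, columns = B types.
#' @export
similarityScores <- function(graph, labelsA, labelsB,
                             direction = c("BtoA", "symmetric")) {
  direction <- match.arg(direction)
  stopifnot(length(labelsB) == nrow(graph$indexB),
            max(graph$indexB) <= length(labelsA))
  if (direction == "symmetric")
    stopifnot(length(labelsA) == nrow(graph$indexA))
  typesA <- sort(unique(as.character(labelsA)))
  typesB <- sort(unique(as.character(labelsB)))
  S <- .scoreMatrix(graph$indexB, labelsA, labelsB, typesA, typesB)
  if (direction == "symmetric") {
    S2 <- .scoreMatrix(graph$indexA, labelsB, labelsA, typesB, typesA)
    S <- (S + Matrix::t(S2)) / 2
  }
  S
}

#' Permutation test for cross-species similarity
#'
#' Shuffles both label vectors independently `nPerm` times (preserving type
#' frequencies) and recomputes the score matrix. A pair is significant when
#' its observed score strictly exceeds all permuted scores -- per-pair
#' comparison under `null = "pair"`, or the maximum permuted score across the
#' whole column of the B type under `null = "rowmax"`. Empirical p-values are
#' `(1 + #{perm >= obs}) / (nPerm + 1)`.
#'
#' @param graph a cross-dataset kNN structure from [crossKNN()].
#' @param labelsA,labelsB cell-type labels.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param null exceedance rule, `"pair"` or `"rowmax"`.
#' @param direction score direction, as in [similarityScores()].
#' @return a [SimilarityResult-class].
#' @export
permutationTest <- function(graph, labelsA, labelsB, nPerm = 1000, seed = 1,
                            null = c("pair", "rowmax"),
                            direction = c("BtoA", "symmetric")) {
  null <- match.arg(null)
  direction <- match.arg(direction)
  stopifnot(nPerm >= 1)
  set.seed(.checkSeed(seed))
  obs <- similarityScores(graph, labelsA, labelsB, direction)
  geCount <- matrix(0L, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  permMaxPair <- matrix(-Inf, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  permMaxCol <- rep(-Inf, ncol(obs))
  for (p in seq_len(nPerm)) {
    S <- similarityScores(graph, sample(labelsA), sample(labelsB), direction)
    geCount <- geCount + (!is.na(S) & !is.na(obs) & S >= obs)
    permMaxPair <- pmax(permMaxPair, S, na.rm = TRUE)
    permMaxCol <- pmax(permMaxCol, apply(S, 2, max, na.rm = TRUE))
  }
  pValues <- (1 + geCount) / (nPerm + 1)
  significant <- if (null == "pair") obs > permMaxPair
                 else sweep(obs, 2, permMaxCol, ">")
  significant[is.na(significant)] <- FALSE
  new("SimilarityResult", scores = obs, pValues = pValues,
      significant = significant, k = graph$k, nPerm = as.integer(nPerm),
      direction = direction, null = null)
}
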