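# Potential scores, directed transitions, vector fields, Moran's I.

makeLineage <- function(seed = 2) {
  lin <- logNormalize(generateLineage(lineageConfig(seed = seed)))
  emb <- embedPCA(lin, nComponents = 20)
  g <- buildKNN(emb, k = 50)
  list(lin = lin, emb = emb, graph = g,
       stage = SummarizedExperiment::colData(lin)$stage)
}

test_that("potential scores recover the planted maturation order", {
  lc <- makeLineage()
  ps <- potentialScores(lc$lin, lc$graph)
  expect_lte(cor(lc$stage, ps$score, method = "spearman"), -0.9)
  expect_equal(range(ps$score), c(0, 1))
  # invariance to gene order and to duplicating a cell
  cnt <- counts(lc$lin)
  shuf <- AnnotatedCounts(cnt[sample(nrow(cnt)), ])
  ps2 <- potentialScores(shuf, lc$graph)
  expect_equal(unname(ps2$score), unname(ps$score))
})

test_that("uniform gene counts give all-equal mid-rank scores", {
  m <- Matrix::sparseMatrix(i = rep(1:5, 4), j = rep(1:4, each = 5), x = 1,
                            dims = c(10, 4))
  ac <- AnnotatedCounts(m)
  g <- buildKNN(matrix(rnorm(8), 4, 2), k = 2)
  ps <- potentialScores(ac, g)
  expect_true(all(ps$score == 0.5))
})

test_that("transition matrix is row-stochastic and directionally biased", {
  lc <- makeLineage()
  ps <- potentialScores(lc$lin, lc$graph)
  Tm <- transitionMatrix(lc$graph, ps, beta = 10)
  expect_lt(max(abs(Matrix::rowSums(Tm) - 1)), 1e-9)
  # beta = 0 reduces to the uniform neighbor kernel
  T0 <- transitionMatrix(lc$graph, ps, beta = 0)
  expect_true(all(abs(T0@x - 1 / lc$graph$k) < 1e-12))
  # softmax concentration: one cell with two neighbors at pseudotime 0 and 1
  g2 <- list(index = rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
             dist = matrix(1, 3, 2), k = 2L, n = 3L,
             barcodes = c("a", "b", "c"))
  class(g2) <- "KnnGraph"
  s <- c(1, 0, 1)          # pseudotime t = 1 - s = (0, 1, 0)
  Tb <- transitionMatrix(g2, s, beta = 10)
  expect_equal(Tb[1, 2], exp(10) / (exp(10) + exp(0)), tolerance = 1e-12)
  expect_gt(Tb[1, 2], 0.999)
  # pseudotime drift is forward for >= 90% of non-terminal cells
  t <- attr(Tm, "pseudotime")
  drift <- as.numeric(Tm %*% t) - t
  nonterm <- lc$stage < max(lc$stage)
  expect_gte(mean(drift[nonterm] >= 0), 0.9)
})

test_that("vector-field projection behaves at its degenerate limits", {
  # symmetric neighborhood at beta = 0: arrow vanishes
  x <- matrix(c(0, -1, 1), ncol = 1)
  g <- list(index = rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
            dist = matrix(1, 3, 2), k = 2L, n = 3L, barcodes = NULL)
  class(g) <- "KnnGraph"
  Tm <- transitionMatrix(g, c(0.5, 0.5, 0.5), beta = 0)
  arr <- projectField(Tm, x)
  expect_equal(arr[1, 1], 0)
  # isolated cell (self-loop row) has a zero arrow
  sl <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1))
  expect_equal(as.numeric(projectField(sl, matrix(5))), 0)
  # arrows point from early to late stages along the lineage
  lc <- makeLineage()
  ps <- potentialScores(lc$lin, lc$graph)
  TmL <- transitionMatrix(lc$graph, ps, beta = 10)
  arrL <- projectField(TmL, lc$emb)
  axis <- vapply(split(seq_along(lc$stage), lc$stage), function(ix)
    colMeans(lc$emb$coordinates[ix, , drop = FALSE]),
    numeric(ncol(lc$emb$coordinates)))
  dirAxis <- axis[, ncol(axis)] - axis[, 1]
  proj <- as.numeric(arrL %*% dirAxis)
  nonterm <- lc$stage < max(lc$stage)
  expect_gte(mean(proj[nonterm] > 0), 0.8)
})

test_that("Moran's I matches a naive double-loop oracle and its null mean", {
  set.seed(9)
  n <- 60
  x <- matrix(rnorm(n * 2), n, 2)
  g <- buildKNN(x, k = 5)
  expr <- matrix(rnorm(8 * n), 8, n)
  expr[1, ] <- x[, 1] + rnorm(n, 0, 0.1)   # spatially smooth gene
  rownames(expr) <- paste0("g", 1:8)
  res <- moranTest(expr, g)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, g$index[i, ]] <- 1
  W <- pmin(A + t(A), 1)
  for (gi in 1:8)
    expect_equal(res$moranI[gi], moranOracle(expr[gi, ], W),
                 tolerance = 1e-10)
  # permuted expression has mean I = -1/(n-1) within Monte-Carlo error
  set.seed(10)
  perms <- replicate(300, moranTest(expr[2, sample(n), drop = FALSE], g)$moranI)
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / (n - 1))), 4 * se)
})

test_that("Moran's I hits its structural extremes on path and cycle graphs", {
  # expression equal to position along a path graph: I near its maximum
  n <- 100
  x <- matrix(seq_len(n), ncol = 1)
  g <- buildKNN(x, k = 2)
  expr <- matrix(as.numeric(x), 1, n, dimnames = list("pos", NULL))
  res <- moranTest(expr, g)
  expect_gt(res$moranI[1], 0.9)
  # alternating +-1 on a cycle: strongly negative autocorrelation
  m <- 20
  W <- matrix(0, m, m)
  for (i in seq_len(m)) {
    W[i, (i %% m) + 1] <- 1
    W[(i %% m) + 1, i] <- 1
  }
  alt <- matrix(rep(c(1, -1), m / 2), 1, m, dimnames = list("alt", NULL))
  resC <- moranTest(alt, Matrix::Matrix(W, sparse = TRUE))
  expect_lt(resC$moranI[1], -0.9)
  # constant genes are flagged and excluded
  cst <- rbind(alt, const = rep(2, m))
  resK <- moranTest(cst, Matrix::Matrix(W, sparse = TRUE))
  expect_true(resK$constant[2])
  expect_true(is.na(resK$q[2]))
})

test_that("trajectory-gene selection applies q then top-N ordering", {
  res <- data.frame(gene = paste0("g", 1:500),
                    moranI = seq(0.99, 0.01, length.out = 500),
                    z = 1, p = 0.001, q = rep(c(0.001, 0.5), c(400, 100)),
                    constant = FALSE)
  sel <- selectTrajectoryGenes(res, qMax = 0.01, topN = 300)
  expect_length(sel, 300)
  expect_identical(sel, paste0("g", 1:300))
  # nothing passes q -> empty
  resNone <- transform(res, q = 0.5)
  expect_length(selectTrajectoryGenes(resNone), 0)
  # fewer than topN pass -> all passing returned in I order
  resFew <- res; resFew$q <- rep(c(0.001, 0.5), c(20, 480))
  expect_identical(selectTrajectoryGenes(resFew), paste0("g", 1:20))
})

test_that("condition comparison of potential is calibrated and powered", {
  set.seed(12)
  # type-I: shuffled condition labels are rarely significant
  hits <- vapply(1:100, function(i) {
    sc <- runif(80)
    cond <- sample(rep(c("control", "plucked"), 40))
    ct <- rep(c("t1", "t2"), each = 40)
    res <- comparePotential(sc, cond, ct)
    any(res$q < 0.05)
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
  # identical scores: difference 0, p = 1
  resEq <- comparePotential(rep(c(0.3, 0.7), 20),
                            rep(c("control", "plucked"), each = 20),
                            rep("t1", 40))
  expect_equal(resEq$medianDiff, 0)
  expect_equal(resEq$p, 1)
  # planted shift at 200 cells per condition is detected
  sc <- c(runif(200), runif(200) + 0.2)
  cond <- rep(c("control", "plucked"), each = 200)
  resP <- comparePotential(sc, cond, rep("t1", 400))
  expect_lt(resP$q, 0.05)
  expect_warning(comparePotential(runif(10), rep(c("a", "b"), each = 5),
                                  rep(c("t1", "t2"), each = 5)),
                 "single condition")
})
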