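# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, closed forms) and never call the code paths they check.

# 12-barcode QC toy with hand-enumerated keep/drop decisions.
# Genes 1:5 are mitochondrial. Expected outcome per barcode:
#   bc1  249 genes detected                    -> drop (low_genes)
#   bc2  250 genes                             -> keep
#   bc3  251 genes                             -> keep
#   bc4  2500 genes                            -> keep
#   bc5  2501 genes                            -> drop (high_genes)
#   bc6  286 genes, mito 15/300 = 0.05 exactly -> keep
#   bc7  285 genes, mito 16/300 > 0.05         -> drop (high_mito)
#   bc8  287 genes, mito 15/301 < 0.05         -> keep
#   bc9  all-zero                              -> drop (low_genes)
#   bc10 1000 genes                            -> keep
#   bc11 2499 genes                            -> keep
#   bc12 101 genes, mito 100/200 = 0.5         -> drop (low_genes;high_mito)
qcToy <- function() {
  nGenes <- 2600
  cols <- list(
    bc1 = cbind(5 + seq_len(249), 1),
    bc2 = cbind(5 + seq_len(250), 1),
    bc3 = cbind(5 + seq_len(251), 1),
    bc4 = cbind(5 + seq_len(2500), 1),
    bc5 = cbind(c(5 + seq_len(2501 - 5), 1:5), 1),
    bc6 = rbind(cbind(5 + seq_len(285), 1), c(1, 15)),
    bc7 = rbind(cbind(5 + seq_len(284), 1), c(1, 16)),
    bc8 = rbind(cbind(5 + seq_len(286), 1), c(1, 15)),
    bc9 = cbind(integer(0), integer(0)),
    bc10 = cbind(5 + seq_len(1000), 1),
    bc11 = cbind(5 + seq_len(2499), 1),
    bc12 = rbind(cbind(5 + seq_len(100), 1), c(1, 100)))
  i <- unlist(lapply(cols, function(x) x[, 1]))
  j <- rep(seq_along(cols), vapply(cols, nrow, 1L))
  x <- unlist(lapply(cols, function(x) x[, 2]))
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nGenes, 12),
                            dimnames = list(paste0("g", seq_len(nGenes)),
                                            names(cols)))
  AnnotatedCounts(m, mito = seq_len(nGenes) <= 5)
}
qcToyKept <- c("bc2", "bc3", "bc4", "bc6", "bc8", "bc10", "bc11")

smallAtlas <- function(seed = 1, nTypes = 3, cells = 50, genes = 300,
                       programSize = 10, logfc = 2) {
  generateAtlas(atlasConfig(nCellTypes = nTypes, cellsPerType = cells,
                            nGenes = genes, programSize = programSize,
                            programLogfc = logfc, seed = seed))
}

# Brute-force kNN oracle: full double loop over pairs.
knnOracle <- function(x, k) {
  n <- nrow(x)
  idx <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) if (j != i) d[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    idx[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  idx
}

# Naive double-loop Moran's I for one expression vector on weights W.
moranOracle <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Brute-force cross-dataset similarity score oracle.
similarityOracle <- function(indexB, labelsA, labelsB) {
  typesA <- sort(unique(labelsA)); typesB <- sort(unique(labelsB))
  S <- matrix(NA_real_, length(typesA), length(typesB),
              dimnames = list(typesA, typesB))
  for (a in typesA) for (b in typesB) {
    cells <- which(labelsB == b)
    cnt <- vapply(cells, function(cb)
      sum(labelsA[indexB[cb, ]] == a), numeric(1))
    S[a, b] <- mean(cnt)
  }
  S
}

# Textbook paired t oracle.
pairedTOracle <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Closed-form one-way ANOVA F oracle.
anovaOracle <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# Build a planted ligand-receptor scenario + matching database on an atlas,
# using moderately expressed background genes (injury-induced regime).
plantedLRSetup <- function(atlas, seed, effect = 4) {
  gn <- baselineModerateGenes(atlas, 4)
  sc <- lrScenario("type_1", "type_2",
                   list(list(ligand = gn[1], receptor = gn[2], pathway = "BMP"),
                        list(ligand = gn[3], receptor = gn[4], pathway = "SPP1")),
                   conditionEffect = effect, timepoints = 3, seed = seed)
  db <- data.frame(id = c("I1", "I2"), ligand = gn[c(1, 3)],
                   receptor = gn[c(2, 4)], pathway = c("BMP", "SPP1"),
                   agonist = "", antagonist = "")
  list(scenario = sc, db = db, genes = gn)
}
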