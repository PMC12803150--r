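# Mass-action/Hill communication probabilities, aggregation, differentials.

toyNet <- function(seed = 1, nPerm = 50) {
  atlas <- smallAtlas(seed = seed, nTypes = 3, cells = 40, genes = 300)
  norm <- logNormalize(atlas)
  db <- readLRDatabase(system.file("extdata", "lr_toy_db.tsv",
                                   package = "regenkit"))
  # graft the database's gene symbols onto the synthetic expression matrix
  m <- as.matrix(SummarizedExperiment::assay(norm, "logcounts"))
  genes <- unique(unlist(strsplit(c(db$ligand, db$receptor, db$agonist,
                                    db$antagonist), "[+,]")))
  genes <- genes[nzchar(genes)]
  rownames(m)[seq_along(genes)] <- genes
  commProbability(m, cellTypes(atlas), db, nPerm = nPerm, seed = seed)
}

test_that("the toy LR database loads and validates", {
  db <- readLRDatabase(system.file("extdata", "lr_toy_db.tsv",
                                   package = "regenkit"))
  expect_equal(nrow(db), 30L)
  expect_setequal(unique(db$pathway),
                  c("Collagen", "MMP", "SlitRobo", "SPP1", "Semaphorin",
                    "Notch", "BMP"))
  bad <- db; bad$ligand[1] <- ""
  expect_error(validateLRDatabase(bad), "empty ligand")
})

test_that("Hill saturation gives P = 0.5 at L*R = Kh and 0 for absent ligand", {
  # two types, one interaction, expression engineered so L*R = Kh
  m <- matrix(0, 3, 40, dimnames = list(c("lig", "rec", "oth"), NULL))
  m[1, 1:20] <- 0.5         # sender ligand level (trimmed mean = value)
  m[2, 21:40] <- 1          # receiver receptor level; L * R = Kh exactly
  m[3, ] <- 1
  labels <- rep(c("S", "R"), each = 20)
  db <- data.frame(id = "I", ligand = "lig", receptor = "rec",
                   pathway = "P", agonist = "", antagonist = "")
  net <- commProbability(m, labels, db, Kh = 0.5, trim = 0, nPerm = 10,
                         seed = 1)
  expect_equal(net@rawProb["S", "R", "I"], 0.5, tolerance = 1e-12)
  # ligand absent in sender: P = 0
  expect_equal(net@rawProb["R", "R", "I"], 0)
  expect_error(commProbability(m, labels, db, Kh = 0), "Kh")
  # raw P is monotone in ligand and receptor levels
  lev <- seq(0, 2, by = 0.5)
  pOf <- function(L, R) (L * R) / (0.5 + L * R)
  grid <- outer(lev, lev, pOf)
  expect_true(all(diff(grid) >= 0) && all(diff(t(grid)) >= 0))
})

test_that("pathway aggregation and centralities conserve tensor mass", {
  net <- toyNet(seed = 2)
  P <- commProb(net)
  pw <- pathwayProbability(net)
  # sum over pathways equals sum over interactions per (sender, receiver)
  expect_equal(apply(pw, c(2, 3), sum), apply(P, c(1, 2), sum),
               tolerance = 1e-12)
  cent <- centralities(net)
  expect_lt(abs(sum(cent$outgoing) - sum(P)), 1e-9)
  expect_lt(abs(sum(cent$incoming) - sum(P)), 1e-9)
  # reproducibility under the seed
  net2 <- toyNet(seed = 2)
  expect_identical(commProb(net2), P)
})

test_that("differential networks vanish for identical inputs and flip sign", {
  net <- toyNet(seed = 3)
  d0 <- diffNetworks(net, net)
  expect_true(all(d0$diffMatrix == 0))
  expect_true(all(d0$diffCentrality$outgoing == 0))
  netB <- toyNet(seed = 4)
  d1 <- diffNetworks(net, netB)
  d2 <- diffNetworks(netB, net)
  expect_equal(d1$diffMatrix, -d2$diffMatrix)
  # identical networks: every pathway difference is zero
  rp <- rankPathways(net, net, commTypes(net)[1], commTypes(net)[2])
  expect_true(all(rp$diff == 0))
})

test_that("a planted condition-specific program is fully recovered", {
  atlas <- smallAtlas(seed = 5, nTypes = 4, cells = 40, genes = 400)
  setup <- plantedLRSetup(atlas, seed = 5)
  tc <- logNormalize(generateLRTimecourse(atlas, setup$scenario,
                                          cellsPerType = 30, timepoints = 3))
  cd <- SummarizedExperiment::colData(tc)
  m <- SummarizedExperiment::assay(tc, "logcounts")
  sel <- function(cond) cd$condition == cond
  netP <- commProbability(m[, sel("plucked")], cd$cell_type[sel("plucked")],
                          setup$db, nPerm = 100, seed = 5)
  netC <- commProbability(m[, sel("control")], cd$cell_type[sel("control")],
                          setup$db, nPerm = 100, seed = 5)
  # the planted interaction is the largest tensor entry and significant
  P <- commProb(netP)
  top <- which(P == max(P), arr.ind = TRUE)[1, ]
  expect_identical(dimnames(P)[[1]][top[1]], "type_1")
  expect_identical(dimnames(P)[[2]][top[2]], "type_2")
  # plucked-vs-control differential: planted pair is the top positive cell
  d <- diffNetworks(netP, netC)
  topD <- which(d$diffMatrix == max(d$diffMatrix), arr.ind = TRUE)[1, ]
  expect_identical(rownames(d$diffMatrix)[topD[1]], "type_1")
  expect_identical(colnames(d$diffMatrix)[topD[2]], "type_2")
  # the planted sender has the largest outgoing centrality delta
  expect_identical(
    d$diffCentrality$cell_type[which.max(d$diffCentrality$outgoing)],
    "type_1")
  # planted pathways rank first for the planted pair
  rp <- rankPathways(netP, netC, "type_1", "type_2")
  expect_true(rp$pathway[1] %in% c("BMP", "SPP1"))
  # differentially expressed signaling genes: ligand recovered, strict bounds
  mSend <- m[, cd$cell_type == "type_1"]
  dl <- diffLRGenes(mSend, cd$condition[cd$cell_type == "type_1"], setup$db)
  expect_true(setup$genes[1] %in% dl$gene[dl$passes & dl$direction == "up"])
  # overexpression gating: planted ligand lands in the sender's set
  oe <- overexpressedGenes(m[, sel("plucked")],
                           cd$cell_type[sel("plucked")], setup$db)
  expect_true(setup$genes[1] %in% oe$type_1)
})

test_that("boundary log2FC exactly 0.25 never passes diffLRGenes", {
  v2 <- 1
  target <- (2^0.25) * (v2 + 1) - 1
  m <- matrix(c(rep(log1p(target), 30), rep(log1p(v2), 30)), 1, 60,
              dimnames = list("ligX", NULL))
  db <- data.frame(id = "I", ligand = "ligX", receptor = "recX",
                   pathway = "P", agonist = "", antagonist = "")
  res <- diffLRGenes(m, rep(c("plucked", "control"), each = 30), db)
  expect_false(any(res$passes))
  # identical groups give an empty pass set
  m2 <- matrix(rep(1, 60), 1, 60, dimnames = list("ligX", NULL))
  res2 <- diffLRGenes(m2, rep(c("plucked", "control"), each = 30), db)
  expect_false(any(res2$passes))
})
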