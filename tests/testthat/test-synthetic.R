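# Generators: determinism, shape, planted-structure moments.

test_that("atlas generation is reproducible and correctly shaped", {
  cfg <- atlasConfig(nCellTypes = 3, cellsPerType = 50, nGenes = 500,
                     programSize = 10, seed = 7)
  a1 <- generateAtlas(cfg)
  a2 <- generateAtlas(cfg)
  expect_identical(as.matrix(counts(a1)), as.matrix(counts(a2)))
  expect_equal(dim(a1), c(500L, 150L))
  expect_equal(length(unique(cellTypes(a1))), 3L)
  expect_error(atlasConfig(nCellTypes = 0), "nCellTypes")
})

test_that("program genes are enriched by exp(programLogfc) in their own type", {
  cfg <- atlasConfig(nCellTypes = 2, cellsPerType = 500, nGenes = 400,
                     programSize = 20, programLogfc = 1.5, seed = 3)
  a <- generateAtlas(cfg)
  m <- as.matrix(counts(a))
  pg <- S4Vectors::metadata(a)$programs$type_1
  own <- rowMeans(m[pg, cellTypes(a) == "type_1"])
  other <- rowMeans(m[pg, cellTypes(a) == "type_2"])
  # ratio of summed program expression vs the closed-form NB mean ratio
  expect_equal(sum(own) / sum(other), exp(1.5), tolerance = 0.1)
  # program sets are disjoint across types
  pr <- S4Vectors::metadata(a)$programs
  expect_length(intersect(pr$type_1, pr$type_2), 0)
})

test_that("species pair plants homologous partners through the gene map", {
  pair <- generateSpeciesPair(
    atlasConfig(nCellTypes = 4, cellsPerType = 60, nGenes = 600,
                programSize = 15, programLogfc = 2, seed = 1),
    sharedFraction = 0.5, seed = 5)
  expect_equal(nrow(pair$truth), 2L)
  expect_true(all(pair$truth$typeA %in% unique(cellTypes(pair$atlasA))))
  expect_true(all(pair$truth$typeB %in% unique(cellTypes(pair$atlasB))))
  expect_true(all(pair$homology$weight > 0 & pair$homology$weight <= 1))
  # projected expression of planted partners correlates more than unrelated
  # types: compare type-mean profiles through the 1:1 gene map
  mA <- as.matrix(counts(pair$atlasA))
  mB <- as.matrix(counts(pair$atlasB))
  profA <- vapply(unique(cellTypes(pair$atlasA)), function(t)
    rowMeans(mA[, cellTypes(pair$atlasA) == t]), numeric(nrow(mA)))
  profB <- vapply(unique(cellTypes(pair$atlasB)), function(t)
    rowMeans(mB[, cellTypes(pair$atlasB) == t]), numeric(nrow(mB)))
  cc <- cor(profA, profB)
  expect_gt(cc["type_1", "Btype_1"], max(cc["type_1", c("Btype_3", "Btype_4")]))
  expect_gt(cc["type_2", "Btype_2"], max(cc["type_2", c("Btype_3", "Btype_4")]))
  expect_error(generateSpeciesPair(atlasConfig(), sharedFraction = 0),
               "sharedFraction")
})

test_that("pool generator honours genotype structure and doublet rate", {
  cfg <- poolConfig(nGenotypes = 3, nucleiPerGenotype = 400, nVariants = 100,
                    meanDepth = 50, doubletRate = 0.1, errorRate = 0,
                    seed = 11)
  pools <- generatePools(cfg)
  # homozygous-alt variants converge to alt fraction 1 at high depth, no error
  g1 <- pools$truth$genotype == 1 & !pools$truth$isDoublet
  homAlt <- which(pools$genotypes[1, ] == 1)
  af <- colSums(altCounts(pools$data)[g1, homAlt, drop = FALSE]) /
    colSums((altCounts(pools$data) + refCounts(pools$data))[g1, homAlt,
                                                            drop = FALSE])
  expect_true(all(af == 1))
  # doublet fraction within a 3-sigma binomial band around the configured rate
  n <- nrow(pools$truth)
  rate <- mean(pools$truth$isDoublet)
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # every genotype pair discordant on >= 20% of variants
  pairs <- combn(3, 2)
  disc <- apply(pairs, 2, function(p)
    mean(pools$genotypes[p[1], ] != pools$genotypes[p[2], ]))
  expect_true(all(disc >= 0.2))
  expect_error(poolConfig(doubletRate = 1), "doubletRate")
})

test_that("LR timecourse plants the condition effect only where stated", {
  atlas <- smallAtlas(seed = 2, nTypes = 3, cells = 40, genes = 300)
  gn <- baselineModerateGenes(atlas, 2, target = 0.5)
  sc <- lrScenario("type_1", "type_2",
                   list(list(ligand = gn[1], receptor = gn[2],
                             pathway = "BMP")),
                   conditionEffect = 3, timepoints = 3, seed = 4)
  tc <- generateLRTimecourse(atlas, sc, cellsPerType = 200,
                             timepoints = c(0, 3))
  cd <- SummarizedExperiment::colData(tc)
  cnt <- as.matrix(counts(tc))
  sender <- cd$cell_type == "type_1"
  lig <- cnt[gn[1], ]
  m <- function(cond, tp) mean(lig[sender & cd$condition == cond &
                                     cd$timepoint == tp])
  expect_equal(m("plucked", 3) / m("control", 3), 3, tolerance = 0.35)
  # unaffected timepoint stays exchangeable
  expect_equal(m("plucked", 0) / m("control", 0), 1, tolerance = 0.35)
  expect_error(generateLRTimecourse(atlas,
    lrScenario("nope", "type_2", sc$interactions)), "senderType")
})

test_that("pulse-chase generator matches its Bernoulli design", {
  cfg <- pulseChaseConfig(nFish = c(X = 8), teethPerQuadrant = 20,
                          baselineReplacementProb = 0.2,
                          pluckedReplacementProb = 0.6, seed = 9)
  tab <- generatePulseChase(cfg)
  cl <- classifyTeeth(tab)
  # replaced teeth are calcein-only; unreplaced carry both dyes
  expect_true(all(cl$status %in% c("old", "new")))
  gains <- toothGain(cl)
  side <- tapply(gains$fishSides$gain, gains$fishSides$side, mean)
  nTeeth <- 8 * 2 * 20
  expect_lt(abs(side["control"] - 0.2), 3 * sqrt(0.2 * 0.8 / nTeeth))
  expect_lt(abs(side["plucked"] - 0.6), 3 * sqrt(0.6 * 0.4 / nTeeth))
  # degenerate probabilities give a deterministic table
  det <- generatePulseChase(pulseChaseConfig(nFish = c(X = 2),
    teethPerQuadrant = 5, baselineReplacementProb = 0,
    pluckedReplacementProb = 1, seed = 1))
  detc <- classifyTeeth(det)
  expect_true(all(detc$status[detc$side == "control"] == "old"))
  expect_true(all(detc$status[detc$side == "plucked"] == "new"))
})
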