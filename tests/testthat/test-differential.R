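# Marker detection, condition DEG thresholds, NB time-course interaction.

test_that("planted program genes are recovered as their type's markers", {
  atlas <- generateAtlas(atlasConfig(nCellTypes = 3, cellsPerType = 200,
                                     nGenes = 500, programSize = 15,
                                     programLogfc = 1, seed = 6))
  norm <- logNormalize(atlas)
  mk <- findMarkers(norm)
  pr <- S4Vectors::metadata(atlas)$programs
  for (t in names(pr)) {
    planted <- rownames(atlas)[pr[[t]]]
    found <- mk$gene[mk$group == t]
    expect_gte(mean(planted %in% found), 0.9)
  }
})

test_that("marker thresholds are applied as stated", {
  # constructed table: gene A expressed in 19% of focal cells (not tested);
  # gene B with log2FC exactly 0.25 (excluded by the strict bound)
  set.seed(3)
  nF <- 100; nR <- 100
  m <- matrix(0, 3, nF + nR)
  m[1, 1:19] <- 5                       # 19% of focal cells
  # gene B: engineered so log2((mean1+1)/(mean2+1)) == 0.25 exactly
  v2 <- 1
  target <- (2^0.25) * (v2 + 1) - 1
  m[2, 1:nF] <- log1p(target)           # already-normalized values
  m[2, nF + 1:nR] <- log1p(v2)
  m[3, 1:nF] <- 3                       # clean marker of the focal group
  rownames(m) <- c("A", "B", "C")
  labels <- rep(c("focal", "rest"), c(nF, nR))
  mk <- findMarkers(m, labels, logfcMin = 0.25, minPct = 0.2, alpha = 0.05)
  focalMk <- mk$gene[mk$group == "focal"]
  expect_false("A" %in% focalMk)        # below min.pct
  expect_false("B" %in% focalMk)        # log2FC not strictly above 0.25
  expect_true("C" %in% focalMk)
  expect_warning(findMarkers(m, rep(c("x", "rest"), c(2, 198))), "fewer")
})

test_that("condition DE applies |log2FC| > 0.25 and p < 0.05 per an oracle", {
  set.seed(4)
  n <- 150
  m <- matrix(rnbinom(40 * 2 * n, mu = 4, size = 2), 40, 2 * n)
  m[1:10, n + 1:n] <- matrix(rnbinom(10 * n, mu = 8, size = 2), 10, n)
  rownames(m) <- paste0("g", 1:40)
  norm <- as.matrix(logNormalize(m + 1))
  cond <- rep(c("control", "plucked"), each = n)
  res <- conditionDE(norm, cond)
  # brute-force oracle: wilcox.test per gene plus threshold application
  for (gi in c(1, 5, 20, 35)) {
    or <- suppressWarnings(wilcox.test(norm[gi, cond == "plucked"],
                                       norm[gi, cond == "control"],
                                       exact = FALSE, correct = FALSE))
    expect_equal(res$p[gi], or$p.value, tolerance = 1e-8)
    m1 <- mean(expm1(norm[gi, cond == "plucked"]))
    m2 <- mean(expm1(norm[gi, cond == "control"]))
    lfc <- log2((m1 + 1) / (m2 + 1))
    expect_equal(res$log2FC[gi], lfc)
    expect_identical(res$deg[gi], abs(lfc) > 0.25 && or$p.value < 0.05)
  }
  # planted 2-fold genes called as up-DEGs with power >= 0.9
  expect_gte(mean(res$deg[1:10] & res$direction[1:10] == "up"), 0.9)
  # identical groups yield an empty DEG set
  resEq <- conditionDE(cbind(norm[, 1:n], norm[, 1:n]), cond)
  expect_false(any(resEq$deg))
  expect_error(conditionDE(norm, rep("plucked", 2 * n)), "both conditions")
})

test_that("log2FC is antisymmetric under group swap and order-invariant", {
  set.seed(5)
  m <- matrix(rpois(30 * 60, 3), 30, 60)
  rownames(m) <- paste0("g", 1:30)
  norm <- as.matrix(logNormalize(m + 1))
  cond <- rep(c("a", "b"), each = 30)
  r1 <- conditionDE(norm, cond, focal = "a")
  r2 <- conditionDE(norm, cond, focal = "b")
  expect_equal(r1$log2FC, -r2$log2FC)
  expect_equal(r1$p, r2$p)
  perm <- sample(60)
  r3 <- conditionDE(norm[, perm], cond[perm], focal = "a")
  expect_equal(r3$deg, r1$deg)
})

test_that("time-course interaction test is calibrated and powered", {
  set.seed(7)
  nPer <- 100
  cond <- rep(c("control", "plucked"), each = 4 * nPer)
  tp <- rep(rep(c(0, 1, 3, 7), each = nPer), 2)
  repl <- rep(rep(c("r1", "r2"), 2 * nPer), 2)
  nGenes <- 150
  mu <- rlnorm(nGenes, 1, 1)
  cnt <- matrix(rnbinom(nGenes * length(cond), mu = mu, size = 2),
                nrow = nGenes)
  boost <- cond == "plucked" & tp == 3
  for (g in 1:30)
    cnt[g, boost] <- rnbinom(sum(boost), mu = mu[g] * exp(1), size = 2)
  res <- timecourseTest(cnt, cond, tp, repl)
  expect_gte(mean(res$significant[1:30]), 0.8)       # planted power
  expect_lte(mean(res$significant[31:nGenes]), 0.07) # null calibration
  # single replicate level: covariate dropped, fit still returned
  one <- timecourseTest(cnt[1:3, , drop = FALSE], cond, tp,
                        rep("r1", length(cond)))
  expect_false(any(is.na(one$p)))
  expect_error(timecourseTest(cnt + 0.5, cond, tp, repl), "integers")
})

test_that("NB regression recovers a planted dispersion", {
  set.seed(8)
  n <- 500
  cond <- rep(c("control", "plucked"), each = n / 2)
  tp <- rep(c(0, 3), n / 2)
  cnt <- matrix(rnbinom(50 * n, mu = 20, size = 2), 50, n)
  res <- timecourseTest(cnt, cond, tp)
  expect_lt(median(abs(res$theta - 2) / 2), 0.25)
})
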