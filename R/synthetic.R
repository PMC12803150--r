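# Synthetic-data generators. Each emits ground truth for recovery tests and
# is bit-reproducible under its seed. Counts are gamma-Poisson (negative
# binomial) with mean mu and variance mu + mu^2/size.

#' Configuration for a synthetic cell-type atlas
#'
#' Defaults emulate the study's jaw atlas at desk scale: 25 cell types with
#' disjoint marker programs, a dedicated mitochondrial gene block whose
#' expected count share is controllable, and shared NB dispersion.
#'
#' @param nCellTypes number of cell types.
#' @param cellsPerType cells simulated per type.
#' @param nGenes total genes (including the mitochondrial block).
#' @param programSize marker genes per type-specific program (disjoint).
#' @param programLogfc mean natural-log fold enrichment of program genes in
#'   their own type.
#' @param nbDispersion NB size parameter, shared across genes.
#' @param librarySizeMean expected total counts per cell.
#' @param mitoFractionMean expected fraction of counts from mitochondrial
#'   genes.
#' @param nMitoGenes size of the flagged mitochondrial block.
#' @param seed integer RNG seed.
#' @return a validated config list of class `AtlasConfig`.
#' @export
atlasConfig <- function(nCellTypes = 25, cellsPerType = 200, nGenes = 2000,
                        programSize = 20, programLogfc = 1.5,
                        nbDispersion = 2, librarySizeMean = 5000,
                        mitoFractionMean = 0.02, nMitoGenes = 10, seed = 1) {
  stopifnot(nCellTypes >= 1, cellsPerType >= 1, nGenes >= 1,
            programSize >= 0, nbDispersion > 0, librarySizeMean > 0,
            mitoFractionMean >= 0, mitoFractionMean < 1, nMitoGenes >= 0,
            nMitoGenes + nCellTypes * programSize <= nGenes)
  structure(list(nCellTypes = as.integer(nCellTypes),
                 cellsPerType = as.integer(cellsPerType),
                 nGenes = as.integer(nGenes),
                 programSize = as.integer(programSize),
                 programLogfc = programLogfc, nbDispersion = nbDispersion,
                 librarySizeMean = librarySizeMean,
                 mitoFractionMean = mitoFractionMean,
                 nMitoGenes = as.integer(nMitoGenes),
                 seed = .checkSeed(seed)),
            class = "AtlasConfig")
}

# Baseline per-gene relative rates plus type-specific multipliers.
# Returns list(rates, mult (genes x types), programs).
.atlasRates <- function(cfg) {
  nG <- cfg$nGenes
  nM <- cfg$nMitoGenes
  # lognormal baseline expression heterogeneity
  w <- rlnorm(nG, meanlog = 0, sdlog = 1)
  if (nM > 0) {
    # scale the mito block so its expected count share is mitoFractionMean
    nonMito <- sum(w[(nM + 1):nG])
    w[seq_len(nM)] <- cfg$mitoFractionMean / (1 - cfg$mitoFractionMean) *
      nonMito * w[seq_len(nM)] / sum(w[seq_len(nM)])
  }
  mult <- matrix(1, nG, cfg$nCellTypes)
  programs <- vector("list", cfg$nCellTypes)
  offset <- nM
  for (t in seq_len(cfg$nCellTypes)) {
    if (cfg$programSize > 0) {
      g <- offset + seq_len(cfg$programSize)
      mult[g, t] <- exp(cfg$programLogfc)
      programs[[t]] <- g
      offset <- offset + cfg$programSize
    } else programs[[t]] <- integer(0)
  }
  list(rates = w, mult = mult, programs = programs)
}

# NB counts for one block of cells of a single type.
# Rates are not renormalized per type, so a program gene's mean in its own
# type is exactly exp(programLogfc) times its mean elsewhere.
.nbBlock <- function(cfg, rates, multCol, nCells) {
  mu <- cfg$librarySizeMean * rates * multCol / sum(rates)
  m <- matrix(rnbinom(cfg$nGenes * nCells, mu = mu, size = cfg$nbDispersion),
              nrow = cfg$nGenes)
  m
}

#' Generate a synthetic cell-type atlas
#'
#' Draws gamma-Poisson counts with disjoint type-specific marker programs and
#' a flagged mitochondrial block; true type labels are attached as
#' `cell_type`.
#'
#' @param config an [atlasConfig()].
#' @return an [AnnotatedCounts-class] with `metadata()$programs` holding the
#'   planted program gene indices per type.
#' @export
generateAtlas <- function(config) {
  stopifnot(inherits(config, "AtlasConfig"))
  set.seed(config$seed)
  plan <- .atlasRates(config)
  blocks <- lapply(seq_len(config$nCellTypes), function(t)
    .nbBlock(config, plan$rates, plan$mult[, t], config$cellsPerType))
  counts <- do.call(cbind, blocks)
  genes <- paste0("gene_", seq_len(config$nGenes))
  if (config$nMitoGenes > 0)
    genes[seq_len(config$nMitoGenes)] <-
      paste0("mt-gene_", seq_len(config$nMitoGenes))
  rownames(counts) <- genes
  colnames(counts) <- paste0("bc", seq_len(ncol(counts)))
  types <- paste0("type_", seq_len(config$nCellTypes))
  ac <- AnnotatedCounts(
    counts,
    cellData = data.frame(
      cell_type = rep(types, each = config$cellsPerType),
      condition = "control", timepoint = 0L),
    mito = seq_len(config$nGenes) <= config$nMitoGenes)
  names(plan$programs) <- types
  metadata(ac)$programs <- plan$programs
  metadata(ac)$config <- config
  ac
}

#' Generate a homologous species pair with a weighted homology table
#'
#' Two atlases whose first `round(sharedFraction * min(types))` cell types
#' share marker programs through 1:1 mapped gene pairs; remaining types get
#' programs on species-private gene blocks so they align with nothing.
#'
#' @param configA,configB [atlasConfig()]s; `nGenes` must agree.
#' @param sharedFraction fraction of (the smaller) type alphabet planted as
#'   homologous, in (0, 1].
#' @param weightRange range of homology weights, drawn uniformly, in (0, 1].
#' @param seed RNG seed.
#' @return list with `atlasA`, `atlasB`, `homology` (data.frame geneA, geneB,
#'   weight), and `truth` (data.frame typeA, typeB of planted partners).
#' @export
generateSpeciesPair <- function(configA, configB = configA,
                                sharedFraction = 1, weightRange = c(0.5, 1),
                                seed = 1) {
  stopifnot(sharedFraction > 0, sharedFraction <= 1,
            configA$nGenes == configB$nGenes)
  seed <- .checkSeed(seed)
  nShared <- max(1L, round(sharedFraction * min(configA$nCellTypes,
                                                configB$nCellTypes)))
  cfgA <- configA; cfgA$seed <- seed
  atlasA <- generateAtlas(cfgA)
  # B reuses A's program layout for shared types; private types are shifted
  # to gene indices beyond A's program region
  cfgB <- configB; cfgB$seed <- seed + 1L
  set.seed(cfgB$seed)
  planB <- .atlasRates(cfgB)
  progA <- metadata(atlasA)$programs
  usedTop <- cfgB$nMitoGenes + cfgB$nCellTypes * cfgB$programSize
  privateOffset <- usedTop
  for (t in seq_len(cfgB$nCellTypes)) {
    planB$mult[, t] <- 1
    if (cfgB$programSize == 0) next
    if (t <= nShared) {
      g <- progA[[t]]
    } else {
      g <- privateOffset + seq_len(cfgB$programSize)
      privateOffset <- privateOffset + cfgB$programSize
      if (max(g) > cfgB$nGenes)
        stop("nGenes too small for species-private programs")
    }
    planB$mult[g, t] <- exp(cfgB$programLogfc)
    planB$programs[[t]] <- g
  }
  blocks <- lapply(seq_len(cfgB$nCellTypes), function(t)
    .nbBlock(cfgB, planB$rates, planB$mult[, t], cfgB$cellsPerType))
  countsB <- do.call(cbind, blocks)
  rownames(countsB) <- paste0("B_gene_", seq_len(cfgB$nGenes))
  colnames(countsB) <- paste0("Bbc", seq_len(ncol(countsB)))
  typesB <- paste0("Btype_", seq_len(cfgB$nCellTypes))
  atlasB <- AnnotatedCounts(
    countsB,
    cellData = data.frame(cell_type = rep(typesB, each = cfgB$cellsPerType)),
    mito = seq_len(cfgB$nGenes) <= cfgB$nMitoGenes)
  names(planB$programs) <- typesB
  metadata(atlasB)$programs <- planB$programs
  homology <- data.frame(
    geneA = rownames(atlasA),
    geneB = rownames(atlasB),
    weight = runif(configA$nGenes, weightRange[1], weightRange[2]))
  truth <- data.frame(typeA = paste0("type_", seq_len(nShared)),
                      typeB = paste0("Btype_", seq_len(nShared)))
  list(atlasA = atlasA, atlasB = atlasB, homology = homology, truth = truth)
}

#' Configuration for a differentiation lineage
#'
#' Encodes the transcriptional-diversity assumption behind gene-count
#' developmental-potential scores: naive cells express more genes, so the
#' expressed-gene count per stage is strictly decreasing.
#'
#' @param nStages number of differentiation stages (>= 2).
#' @param genesOnAtStage strictly decreasing integer vector of expressed-gene
#'   counts per stage; default a linear ramp from 80% to 20% of `nGenes`.
#' @param cellsPerStage cells per stage.
#' @param nGenes gene universe size.
#' @param librarySizeMean expected counts per cell.
#' @param nbDispersion NB size parameter.
#' @param seed RNG seed.
#' @export
lineageConfig <- function(nStages = 5, genesOnAtStage = NULL,
                          cellsPerStage = 20, nGenes = 1000,
                          librarySizeMean = 3000, nbDispersion = 2,
                          seed = 1) {
  stopifnot(nStages >= 2)
  if (is.null(genesOnAtStage))
    genesOnAtStage <- round(seq(0.8, 0.2, length.out = nStages) * nGenes)
  stopifnot(length(genesOnAtStage) == nStages, all(diff(genesOnAtStage) < 0),
            all(genesOnAtStage >= 1), max(genesOnAtStage) <= nGenes)
  structure(list(nStages = as.integer(nStages),
                 genesOnAtStage = as.integer(genesOnAtStage),
                 cellsPerStage = as.integer(cellsPerStage),
                 nGenes = as.integer(nGenes),
                 librarySizeMean = librarySizeMean,
                 nbDispersion = nbDispersion, seed = .checkSeed(seed)),
            class = "LineageConfig")
}

#' Generate a differentiation lineage with a maturation gradient
#'
#' Stage `s` cells express the first `genesOnAtStage[s]` genes (nested, so
#' neighboring stages overlap and the kNN graph chains them); counts are NB.
#' The true stage index is attached as `stage` (0-based, 0 = most naive) and
#' doubles as the `timepoint` annotation.
#'
#' @param config a [lineageConfig()].
#' @return an [AnnotatedCounts-class] with `colData()$stage`.
#' @export
generateLineage <- function(config) {
  stopifnot(inherits(config, "LineageConfig"))
  set.seed(config$seed)
  w <- rlnorm(config$nGenes, 0, 0.5)
  blocks <- lapply(seq_len(config$nStages), function(s) {
    on <- config$genesOnAtStage[s]
    rates <- w * (seq_len(config$nGenes) <= on)
    mu <- config$librarySizeMean * rates / sum(rates)
    matrix(rnbinom(config$nGenes * config$cellsPerStage, mu = mu,
                   size = config$nbDispersion), nrow = config$nGenes)
  })
  counts <- do.call(cbind, blocks)
  rownames(counts) <- paste0("gene_", seq_len(config$nGenes))
  colnames(counts) <- paste0("bc", seq_len(ncol(counts)))
  stage <- rep(seq_len(config$nStages) - 1L, each = config$cellsPerStage)
  ac <- AnnotatedCounts(counts,
                        cellData = data.frame(cell_type = paste0("stage_", stage),
                                              timepoint = stage,
                                              stage = stage))
  metadata(ac)$config <- config
  ac
}

#' Configuration for a pooled-genotype experiment
#'
#' Emulates the study's pooling design: 2-4 individuals per pool, sparse
#' variant coverage per nucleus, sequencing-error allele flips, and a small
#' doublet rate.
#'
#' @param nGenotypes individuals per pool (2-4).
#' @param nucleiPerGenotype nuclei per individual.
#' @param nVariants shared variants.
#' @param meanDepth expected reads covering a variant in a nucleus.
#' @param doubletRate fraction of nuclei that are two-genotype doublets, in
#'   `[0, 1)`.
#' @param errorRate per-read allele flip probability, in `[0, 0.5)`.
#' @param seed RNG seed.
#' @export
poolConfig <- function(nGenotypes = 3, nucleiPerGenotype = 300,
                       nVariants = 200, meanDepth = 5, doubletRate = 0.05,
                       errorRate = 0.01, seed = 1) {
  stopifnot(nGenotypes >= 2, nGenotypes <= 4, nucleiPerGenotype >= 1,
            nVariants >= 1, meanDepth > 0,
            doubletRate >= 0, doubletRate < 1,
            errorRate >= 0, errorRate < 0.5)
  structure(list(nGenotypes = as.integer(nGenotypes),
                 nucleiPerGenotype = as.integer(nucleiPerGenotype),
                 nVariants = as.integer(nVariants), meanDepth = meanDepth,
                 doubletRate = doubletRate, errorRate = errorRate,
                 seed = .checkSeed(seed)),
            class = "PoolConfig")
}

#' Generate pooled-nucleus allele counts with known genotype truth
#'
#' Genotype alt-allele fractions live in `{0, 0.5, 1}` per variant, with at
#' least 20% of variants discordant between every genotype pair. Doublets mix
#' two distinct genotypes with equal weight. Depth is Poisson(`meanDepth`)
#' per (nucleus, variant); alt reads are binomial around the (error-flipped)
#' expected alt fraction.
#'
#' @param config a [poolConfig()].
#' @return list with `data` ([AlleleCountData-class]), `truth` (data.frame
#'   barcode, genotype, genotype2, isDoublet), and `genotypes` (the K x V
#'   alt-fraction matrix).
#' @export
generatePools <- function(config) {
  stopifnot(inherits(config, "PoolConfig"))
  set.seed(config$seed)
  K <- config$nGenotypes; V <- config$nVariants
  repeat {
    G <- matrix(sample(c(0, 0.5, 1), K * V, replace = TRUE), K, V)
    pairs <- combn(K, 2)
    disc <- apply(pairs, 2, function(p) mean(G[p[1], ] != G[p[2], ]))
    if (all(disc >= 0.2)) break
  }
  nNuc <- K * config$nucleiPerGenotype
  g1 <- rep(seq_len(K), each = config$nucleiPerGenotype)
  isDoublet <- runif(nNuc) < config$doubletRate
  g2 <- rep(NA_integer_, nNuc)
  g2[isDoublet] <- vapply(g1[isDoublet], function(g)
    sample(setdiff(seq_len(K), g), 1L), integer(1))
  frac <- G[g1, , drop = FALSE]
  if (any(isDoublet))
    frac[isDoublet, ] <- (G[g1[isDoublet], , drop = FALSE] +
                          G[g2[isDoublet], , drop = FALSE]) / 2
  e <- config$errorRate
  frac <- frac * (1 - e) + (1 - frac) * e
  depth <- matrix(rpois(nNuc * V, config$meanDepth), nNuc, V)
  alt <- matrix(rbinom(nNuc * V, depth, frac), nNuc, V)
  ref <- depth - alt
  bcs <- paste0("nuc_", seq_len(nNuc))
  vars <- paste0("var_", seq_len(V))
  dimnames(ref) <- dimnames(alt) <- list(bcs, vars)
  data <- AlleleCountData(as(ref, "CsparseMatrix"), as(alt, "CsparseMatrix"))
  truth <- data.frame(barcode = bcs, genotype = g1, genotype2 = g2,
                      isDoublet = isDoublet)
  list(data = data, truth = truth, genotypes = G)
}

#' Ligand-receptor perturbation scenario
#'
#' Describes a planted condition-specific signaling program: in the plucked
#' condition at the listed timepoints, ligand genes are up-regulated in the
#' sender type and receptor genes in the receiver type by `conditionEffect`.
#'
#' @param senderType,receiverType cell-type labels in the atlas.
#' @param interactions list of `list(ligand=, receptor=, pathway=)`, each a
#'   character vector of subunit genes plus a pathway name.
#' @param conditionEffect multiplicative up-regulation, >= 1.
#' @param timepoints timepoints affected (default 1, 3, 7 -- the post-pluck
#'   response window).
#' @param seed RNG seed.
#' @export
lrScenario <- function(senderType, receiverType, interactions,
                       conditionEffect = 3, timepoints = c(1, 3, 7),
                       seed = 1) {
  stopifnot(conditionEffect >= 1, length(interactions) >= 1)
  structure(list(senderType = senderType, receiverType = receiverType,
                 interactions = interactions,
                 conditionEffect = conditionEffect,
                 timepoints = timepoints, seed = .checkSeed(seed)),
            class = "LRScenario")
}

#' Generate a condition-by-timepoint expression series with a planted
#' ligand-receptor program
#'
#' Resamples NB counts from the atlas's per-type gene means for each
#' condition in `{control, plucked}` crossed with timepoints `{0, 1, 3, 7}`.
#' The scenario's ligand genes (in the sender type) and receptor genes (in
#' the receiver type) are scaled by `conditionEffect` only in plucked cells
#' at the affected timepoints. Cells are split over `nReplicates` individuals
#' with a mild lognormal replicate effect.
#'
#' @param atlas an [AnnotatedCounts-class] with `cell_type` labels.
#' @param scenario an [lrScenario()]; set `conditionEffect = 1` for a null.
#' @param cellsPerType cells per type per condition-timepoint combination.
#' @param timepoints timepoints simulated.
#' @param nReplicates individuals per condition-timepoint.
#' @param replicateSd sd of the lognormal per-replicate library-size effect.
#' @return an [AnnotatedCounts-class] with `condition`, `timepoint`,
#'   `individual` annotations.
#' @export
generateLRTimecourse <- function(atlas, scenario, cellsPerType = 50,
                                 timepoints = c(0, 1, 3, 7),
                                 nReplicates = 2, replicateSd = 0.1) {
  stopifnot(inherits(scenario, "LRScenario"))
  types <- unique(cellTypes(atlas))
  stopifnot(scenario$senderType %in% types, scenario$receiverType %in% types)
  allGenes <- unlist(lapply(scenario$interactions,
                            function(x) c(x$ligand, x$receptor)))
  if (!all(allGenes %in% rownames(atlas)))
    stop("scenario genes missing from the atlas")
  set.seed(scenario$seed)
  cfg <- metadata(atlas)$config
  size <- if (!is.null(cfg)) cfg$nbDispersion else 2
  cnt <- as.matrix(counts(atlas))
  typeMeans <- vapply(types, function(t)
    rowMeans(cnt[, cellTypes(atlas) == t, drop = FALSE]),
    numeric(nrow(atlas)))
  ligGenes <- unique(unlist(lapply(scenario$interactions, `[[`, "ligand")))
  recGenes <- unique(unlist(lapply(scenario$interactions, `[[`, "receptor")))
  blocks <- list(); cd <- list()
  for (cond in c("control", "plucked")) for (tp in timepoints) {
    for (t in types) {
      mu <- typeMeans[, t]
      if (cond == "plucked" && tp %in% scenario$timepoints) {
        if (t == scenario$senderType)
          mu[ligGenes] <- mu[ligGenes] * scenario$conditionEffect
        if (t == scenario$receiverType)
          mu[recGenes] <- mu[recGenes] * scenario$conditionEffect
      }
      repId <- sample(rep_len(seq_len(nReplicates), cellsPerType))
      repEff <- rlnorm(nReplicates, 0, replicateSd)[repId]
      m <- matrix(rnbinom(length(mu) * cellsPerType,
                          mu = outer(mu, repEff), size = size),
                  nrow = length(mu))
      blocks[[length(blocks) + 1L]] <- m
      cd[[length(cd) + 1L]] <- data.frame(
        cell_type = t, condition = cond, timepoint = tp,
        individual = paste0(cond, "_t", tp, "_rep", repId))
    }
  }
  countsAll <- do.call(cbind, blocks)
  rownames(countsAll) <- rownames(atlas)
  colnames(countsAll) <- paste0("bc", seq_len(ncol(countsAll)))
  ac <- AnnotatedCounts(countsAll, cellData = do.call(rbind, cd),
                        mito = mitoGenes(atlas))
  metadata(ac)$scenario <- scenario
  ac
}

#' Pick moderately expressed background genes for a planted scenario
#'
#' Injury-induced signaling genes are near-quiescent at baseline and switched
#' on by the perturbation; a constitutively high ligand-receptor pair barely
#' moves under Hill saturation. This helper returns background genes (not in
#' any type program, not mitochondrial) whose baseline log-normalized mean is
#' closest to `target`, the regime where a few-fold induction converts a
#' non-significant interaction into a strong one.
#'
#' @param atlas an [AnnotatedCounts-class] from [generateAtlas()].
#' @param n genes to return.
#' @param target baseline log-normalized mean aimed for.
#' @return character vector of gene names.
#' @export
baselineModerateGenes <- function(atlas, n, target = 0.25) {
  norm <- logNormalize(atlas)
  m <- .asDense(assay(norm, "logcounts"))
  excl <- unique(c(which(mitoGenes(atlas)),
                   unlist(metadata(atlas)$programs)))
  bg <- setdiff(seq_len(nrow(atlas)), excl)
  lv <- rowMeans(m[bg, , drop = FALSE])
  rownames(atlas)[bg[order(abs(lv - target))][seq_len(n)]]
}

#' Configuration for a pulse-chase tooth-replacement experiment
#'
#' Defaults mirror the study design: three species with 8, 8 and 9 fish,
#' teeth plucked on the right side of both jaws with the left side as
#' internal control, and a plucked-side replacement probability about 3.5x
#' baseline (so roughly 60% of plucked-side teeth are new after the chase).
#'
#' @param nFish named integer vector, fish per species.
#' @param teethPerQuadrant teeth scored per jaw quadrant.
#' @param baselineReplacementProb per-tooth replacement probability on the
#'   control side during the chase.
#' @param pluckedReplacementProb same on the plucked side; must be >= baseline.
#' @param seed RNG seed.
#' @export
pulseChaseConfig <- function(nFish = c(MZ = 8L, CA = 8L, PT = 9L),
                             teethPerQuadrant = 12,
                             baselineReplacementProb = 0.17,
                             pluckedReplacementProb = 0.60, seed = 1) {
  stopifnot(all(nFish >= 1), teethPerQuadrant >= 1,
            baselineReplacementProb >= 0, baselineReplacementProb <= 1,
            pluckedReplacementProb >= baselineReplacementProb,
            pluckedReplacementProb <= 1)
  if (is.null(names(nFish)))
    names(nFish) <- paste0("sp", seq_along(nFish))
  structure(list(nFish = setNames(as.integer(nFish), names(nFish)),
                 teethPerQuadrant = as.integer(teethPerQuadrant),
                 baselineReplacementProb = baselineReplacementProb,
                 pluckedReplacementProb = pluckedReplacementProb,
                 seed = .checkSeed(seed)),
            class = "PulseChaseConfig")
}

#' Generate a pulse-chase tooth table
#'
#' Per tooth, replacement during the chase is Bernoulli at the side-specific
#' probability. Replaced teeth mineralized after the Alizarin pulse, so they
#' are Calcein-only; unreplaced teeth carry both dyes.
#'
#' @param config a [pulseChaseConfig()].
#' @return a `ToothTable` data.frame with columns fish, species, jaw, side,
#'   quadrant, tooth, alizarin, calcein.
#' @export
generatePulseChase <- function(config) {
  stopifnot(inherits(config, "PulseChaseConfig"))
  set.seed(config$seed)
  rows <- list()
  for (sp in names(config$nFish)) for (f in seq_len(config$nFish[[sp]])) {
    fish <- paste0(sp, "_f", f)
    for (jaw in c("upper", "lower")) for (side in c("control", "plucked")) {
      p <- if (side == "plucked") config$pluckedReplacementProb
           else config$baselineReplacementProb
      replaced <- runif(config$teethPerQuadrant) < p
      rows[[length(rows) + 1L]] <- data.frame(
        fish = fish, species = sp, jaw = jaw, side = side,
        quadrant = paste(fish, jaw, side, sep = "_"),
        tooth = seq_len(config$teethPerQuadrant),
        alizarin = !replaced, calcein = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
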