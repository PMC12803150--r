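# Ligand-receptor communication: mass-action/Hill probabilities with
# permutation significance, pathway aggregation, centralities, and the
# plucked-vs-control differential comparison.

#' Read a ligand-receptor interaction database
#'
#' Tab-separated (or JSON) table with columns `id`, `ligand`, `receptor`,
#' `pathway` and optional `agonist`, `antagonist`. Multi-subunit ligands and
#' receptors are `+`-separated gene lists; cofactor columns are
#' `,`-separated gene sets.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`).
#' @return a validated `LRDatabase` data.frame.
#' @export
readLRDatabase <- function(path) {
  db <- if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite required to read JSON databases")
    as.data.frame(jsonlite::fromJSON(path))
  } else read.delim(path, stringsAsFactors = FALSE)
  validateLRDatabase(db)
}

#' @rdname readLRDatabase
#' @param db data.frame to validate in place.
#' @export
validateLRDatabase <- function(db) {
  stopifnot(all(c("id", "ligand", "receptor", "pathway") %in% colnames(db)))
  if (any(!nzchar(db$ligand)) || any(!nzchar(db$receptor)))
    stop("empty ligand or receptor subunit list")
  if (any(!nzchar(db$pathway))) stop("empty pathway name")
  if (anyDuplicated(db$id)) stop("interaction ids must be unique")
  for (col in c("agonist", "antagonist"))
    if (is.null(db[[col]])) db[[col]] <- ""
  db
}

.splitGenes <- function(s, sep = "\\+") {
  lapply(strsplit(as.character(s), sep), function(x) x[nzchar(x)])
}

# All genes referenced by a database.
.dbGenes <- function(db) {
  unique(c(unlist(.splitGenes(db$ligand)), unlist(.splitGenes(db$receptor)),
           unlist(.splitGenes(db$agonist, ",")),
           unlist(.splitGenes(db$antagonist, ","))))
}

#' Per-type overexpressed signaling genes
#'
#' One-vs-rest one-sided (greater) Wilcoxon rank-sum test restricted to the
#' genes of the ligand-receptor database. Used to gate communication
#' inference: an interaction proceeds only where at least one participating
#' gene is overexpressed in the sender or the receiver.
#'
#' @param norm normalized genes x cells matrix or [AnnotatedCounts-class]
#'   with `logcounts`.
#' @param labels per-cell type labels.
#' @param db an `LRDatabase` data.frame.
#' @param alpha raw p threshold.
#' @return named list of gene sets, one per cell type.
#' @export
overexpressedGenes <- function(norm, labels = NULL, db, alpha = 0.05) {
  if (is.null(labels) && is(norm, "AnnotatedCounts")) labels <- cellTypes(norm)
  m <- .asDense(.normMatrix(norm))
  labels <- as.character(labels)
  types <- sort(unique(labels))
  stopifnot(length(types) >= 2)
  genes <- intersect(.dbGenes(db), rownames(m))
  sets <- lapply(types, function(ct) {
    if (!length(genes)) return(character(0))
    rs <- .rankSumRows(m[genes, , drop = FALSE], labels == ct)
    genes[rs$p.greater < alpha]
  })
  names(sets) <- types
  sets
}

# Per-type trimmed-mean expression for a set of genes; genes missing from
# the matrix contribute zero. Returns genes x types.
.typeLevels <- function(m, labels, genes, trim) {
  types <- sort(unique(labels))
  lev <- matrix(0, length(genes), length(types),
                dimnames = list(genes, types))
  present <- genes[genes %in% rownames(m)]
  for (ct in types) {
    sub <- m[present, labels == ct, drop = FALSE]
    lev[present, ct] <- apply(sub, 1, mean, trim = trim)
  }
  lev
}

# geometric mean of subunit rows of a level matrix (types as columns);
# any zero subunit zeroes the complex, single subunits pass through exactly
.subunitLevel <- function(lev, subunits) {
  if (!length(subunits)) return(rep(0, ncol(lev)))
  sub <- lev[subunits, , drop = FALSE]
  if (length(subunits) == 1L) return(as.numeric(sub))
  out <- numeric(ncol(lev))
  pos <- colSums(sub == 0) == 0
  if (any(pos)) out[pos] <- exp(colMeans(log(sub[, pos, drop = FALSE])))
  out
}

# Raw probability tensor for one labeling. lev: dbGenes x types trimmed
# means. Returns senders x receivers x interactions.
.probTensor <- function(lev, db, Kh) {
  types <- colnames(lev)
  nT <- length(types); nI <- nrow(db)
  P <- array(0, c(nT, nT, nI), dimnames = list(types, types, db$id))
  ligList <- .splitGenes(db$ligand)
  recList <- .splitGenes(db$receptor)
  agoList <- .splitGenes(db$agonist, ",")
  antList <- .splitGenes(db$antagonist, ",")
  for (i in seq_len(nI)) {
    L <- .subunitLevel(lev, ligList[[i]])     # per sender type
    R <- .subunitLevel(lev, recList[[i]])     # per receiver type
    LR <- outer(L, R)
    if (length(agoList[[i]])) {
      a <- colMeans(lev[intersect(agoList[[i]], rownames(lev)), , drop = FALSE])
      AG <- outer(a / (Kh + a), a / (Kh + a), function(x, y) (x + y) / 2)
      LR <- LR * (1 + AG)
    }
    if (length(antList[[i]])) {
      a <- colMeans(lev[intersect(antList[[i]], rownames(lev)), , drop = FALSE])
      ANT <- outer(a / (Kh + a), a / (Kh + a), function(x, y) (x + y) / 2)
      LR <- LR / (1 + ANT)
    }
    P[, , i] <- LR / (Kh + LR)
  }
  P
}

#' Infer a cell-cell communication network
#'
#' The communication probability of interaction `i` from sender `s` to
#' receiver `r` follows the law of mass action with Hill saturation:
#' the ligand level (trimmed-mean expression in `s`, geometric mean over
#' subunits) times the receptor level in `r`, modulated by agonist and
#' antagonist cofactors, saturated as `LR / (Kh + LR)`. Significance is
#' assessed by `nPerm` cell-label permutations (p = fraction of permuted
#' tensors >= observed); probabilities with `p >= alpha` are set to zero
#' before any downstream aggregation.
#'
#' @param norm normalized genes x cells matrix or [AnnotatedCounts-class]
#'   with `logcounts`.
#' @param labels per-cell type labels.
#' @param db `LRDatabase` data.frame. Genes absent from the matrix are
#'   treated as unexpressed, with a warning.
#' @param Kh Hill half-saturation constant (> 0).
#' @param trim trimmed-mean fraction per tail.
#' @param nPerm label permutations.
#' @param seed RNG seed.
#' @param alpha significance threshold for masking.
#' @param overexpressed optional output of [overexpressedGenes()]; when
#'   given, interactions with no participating gene overexpressed in sender
#'   or receiver are zeroed.
#' @return a [CommunicationNetwork-class].
#' @export
commProbability <- function(norm, labels = NULL, db, Kh = 0.5, trim = 0.1,
                            nPerm = 100, seed = 1, alpha = 0.05,
                            overexpressed = NULL) {
  if (Kh <= 0) stop("Kh must be positive")
  if (is.null(labels) && is(norm, "AnnotatedCounts")) labels <- cellTypes(norm)
  m <- .asDense(.normMatrix(norm))
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m))
  db <- validateLRDatabase(db)
  genes <- .dbGenes(db)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    warning(length(missing), " database genes absent; treated as unexpressed")
  set.seed(.checkSeed(seed))
  lev <- .typeLevels(m, labels, genes, trim)
  P <- .probTensor(lev, db, Kh)
  geCount <- array(0L, dim(P))
  for (b in seq_len(nPerm)) {
    levP <- .typeLevels(m, sample(labels), genes, trim)
    geCount <- geCount + (.probTensor(levP, db, Kh) >= P)
  }
  pv <- geCount / nPerm
  masked <- P
  masked[pv >= alpha] <- 0
  if (!is.null(overexpressed)) {
    ligList <- .splitGenes(db$ligand); recList <- .splitGenes(db$receptor)
    types <- colnames(lev)
    for (i in seq_len(nrow(db))) for (s in seq_along(types))
      for (r in seq_along(types)) {
        ok <- any(ligList[[i]] %in% overexpressed[[types[s]]]) ||
              any(recList[[i]] %in% overexpressed[[types[r]]])
        if (!ok) masked[s, r, i] <- 0
      }
  }
  new("CommunicationNetwork", prob = masked, rawProb = P,
      pValues = array(pv, dim(P), dimnames = dimnames(P)),
      pathways = as.character(db$pathway),
      params = list(Kh = Kh, trim = trim, nPerm = nPerm, alpha = alpha,
                    seed = seed))
}

#' Pathway-level communication probabilities
#'
#' Sums the significance-masked interaction probabilities within each
#' pathway, per (sender, receiver) pair.
#'
#' @param net a [CommunicationNetwork-class].
#' @return 3-d array pathway x sender x receiver.
#' @export
pathwayProbability <- function(net) {
  P <- commProb(net)
  paths <- sort(unique(net@pathways))
  out <- array(0, c(length(paths), dim(P)[1], dim(P)[2]),
               dimnames = list(paths, dimnames(P)[[1]], dimnames(P)[[2]]))
  for (pw in paths)
    out[pw, , ] <- apply(P[, , net@pathways == pw, drop = FALSE], c(1, 2), sum)
  out
}

#' Incoming and outgoing interaction strengths per cell type
#'
#' Outgoing strength of a type is its total significance-masked probability
#' as a sender, summed over receivers and interactions; incoming is the
#' mirror. Both sums equal the total tensor mass.
#'
#' @param net a [CommunicationNetwork-class].
#' @return data.frame (cell_type, outgoing, incoming).
#' @export
centralities <- function(net) {
  P <- commProb(net)
  data.frame(cell_type = dimnames(P)[[1]],
             outgoing = apply(P, 1, sum),
             incoming = apply(P, 2, sum), row.names = NULL)
}

#' Differential communication between conditions
#'
#' All deltas are plucked minus control: the differential interaction matrix
#' sums probabilities over interactions per (sender, receiver); differential
#' centralities subtract per type. Run once per timepoint on networks built
#' from that timepoint's cells.
#'
#' @param netPlucked,netControl [CommunicationNetwork-class] objects over
#'   the same type alphabet and database.
#' @return object of class `DiffCommResult`: list with `diffMatrix`
#'   (senders x receivers), `diffCentrality` (data.frame), `diffCount`
#'   (difference in numbers of significant interactions).
#' @export
diffNetworks <- function(netPlucked, netControl) {
  Pp <- commProb(netPlucked); Pc <- commProb(netControl)
  if (!identical(dimnames(Pp), dimnames(Pc)))
    stop("networks have mismatched type alphabets or databases")
  diffMatrix <- apply(Pp, c(1, 2), sum) - apply(Pc, c(1, 2), sum)
  cp <- centralities(netPlucked); cc <- centralities(netControl)
  diffCentrality <- data.frame(cell_type = cp$cell_type,
                               outgoing = cp$outgoing - cc$outgoing,
                               incoming = cp$incoming - cc$incoming)
  diffCount <- apply(Pp > 0, c(1, 2), sum) - apply(Pc > 0, c(1, 2), sum)
  structure(list(diffMatrix = diffMatrix, diffCentrality = diffCentrality,
                 diffCount = diffCount),
            class = "DiffCommResult")
}

#' Rank pathway differences for one sender-receiver pair
#'
#' Information flow (summed significant probability) per pathway in each
#' condition for the given pair, the difference and relative difference,
#' sorted by decreasing absolute difference. Pathways silent in both
#' conditions are excluded; condition-exclusive pathways are flagged.
#'
#' @param netPlucked,netControl [CommunicationNetwork-class] objects.
#' @param sender,receiver cell-type labels present in both networks.
#' @return data.frame (pathway, plucked, control, diff, relDiff, exclusive).
#' @export
rankPathways <- function(netPlucked, netControl, sender, receiver) {
  pp <- pathwayProbability(netPlucked)
  pc <- pathwayProbability(netControl)
  if (!sender %in% dimnames(pp)[[2]] || !receiver %in% dimnames(pp)[[3]] ||
      !sender %in% dimnames(pc)[[2]] || !receiver %in% dimnames(pc)[[3]])
    stop("sender/receiver pair absent from a network")
  paths <- union(dimnames(pp)[[1]], dimnames(pc)[[1]])
  p1 <- setNames(rep(0, length(paths)), paths)
  p0 <- p1
  p1[dimnames(pp)[[1]]] <- pp[, sender, receiver]
  p0[dimnames(pc)[[1]]] <- pc[, sender, receiver]
  keep <- p1 > 0 | p0 > 0
  p1 <- p1[keep]; p0 <- p0[keep]
  d <- p1 - p0
  rel <- ifelse(p1 + p0 > 0, d / ((p1 + p0) / 2), 0)
  out <- data.frame(pathway = names(p1), plucked = unname(p1),
                    control = unname(p0), diff = unname(d),
                    relDiff = unname(rel),
                    exclusive = ifelse(p1 > 0 & p0 == 0, "plucked",
                                ifelse(p0 > 0 & p1 == 0, "control", "")))
  out[order(-abs(out$diff)), , drop = FALSE]
}

#' Differentially expressed signaling genes between conditions
#'
#' Rank-sum test restricted to the database's genes within one cell type;
#' a gene passes when `p < alpha` and `|log2FC| > logfcMin` (both strict).
#'
#' @param norm normalized genes x cells matrix (one cell type).
#' @param condition per-cell condition labels.
#' @param db `LRDatabase` data.frame.
#' @param logfcMin,alpha strict thresholds.
#' @return data.frame (gene, log2FC, p, passes, direction).
#' @export
diffLRGenes <- function(norm, condition, db, logfcMin = 0.25, alpha = 0.05) {
  m <- .asDense(.normMatrix(norm))
  genes <- intersect(.dbGenes(db), rownames(m))
  if (!length(genes))
    return(data.frame(gene = character(), log2FC = numeric(), p = numeric(),
                      passes = logical(), direction = character()))
  res <- conditionDE(m[genes, , drop = FALSE], condition,
                     logfcMin = logfcMin, alpha = alpha)
  data.frame(gene = res$gene, log2FC = res$log2FC, p = res$p,
             passes = res$deg, direction = res$direction)
}
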