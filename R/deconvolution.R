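# Pooled-genotype deconvolution: binomial-mixture EM over cluster-specific
# alt-allele fractions, doublet hypotheses as averaged fraction pairs, and
# the dual-run consensus retention rule.

# log binomial evidence of every nucleus under a given alt-fraction vector.
# alt, dep: nuclei x variants sparse; f: length-V fractions (clipped).
.binomLogLik <- function(alt, dep, f) {
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  as.numeric(alt %*% log(f) + (dep - alt) %*% log(1 - f))
}

#' Cluster pooled nuclei by genotype (binomial-mixture EM)
#'
#' Fits `k` genotype clusters, each a vector of per-variant alt-allele
#' fractions, by EM on the per-(nucleus, variant) binomial likelihood of the
#' alt/ref counts. After convergence, every nucleus is scored under the `k`
#' singlet hypotheses plus one doublet hypothesis per cluster pair (allele
#' fractions averaged), with prior mass `doubletPrior` spread over doublet
#' hypotheses. The best of `nRestarts` EM fits by total log-likelihood is
#' kept; the total log-likelihood is asserted non-decreasing at every
#' iteration. Cluster labels are arbitrary up to permutation.
#'
#' @param data an [AlleleCountData-class].
#' @param k number of genotype clusters, 2-8.
#' @param seed RNG seed (restart initialization).
#' @param nRestarts random restarts.
#' @param maxIter,tol EM stopping rule.
#' @param doubletPrior prior probability that a nucleus is a doublet.
#' @return a [GenotypeAssignment-class]. Nuclei with zero total coverage are
#'   labeled `"unassigned"` with a flat posterior.
#' @export
clusterGenotypes <- function(data, k, seed = 1, nRestarts = 10,
                             maxIter = 200, tol = 1e-6,
                             doubletPrior = 0.05) {
  stopifnot(is(data, "AlleleCountData"), k >= 2, k <= 8)
  alt <- altCounts(data); ref <- refCounts(data)
  dep <- alt + ref
  n <- nrow(alt)
  if (k > n) stop("more clusters than nuclei")
  covered <- Matrix::rowSums(dep) > 0
  set.seed(.checkSeed(seed))
  altC <- alt[covered, , drop = FALSE]
  depC <- dep[covered, , drop = FALSE]
  nC <- nrow(altC)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    # init: random hard assignment -> M-step
    resp <- matrix(0, nC, k)
    resp[cbind(seq_len(nC), sample(k, nC, replace = TRUE))] <- 1
    prevLL <- -Inf
    trace <- numeric(0)
    a <- 0.5  # Beta(1/2, 1/2) pseudocounts stabilize rarely-covered variants
    for (iter in seq_len(maxIter)) {
      # M-step: MAP fraction per (cluster, variant)
      f <- vapply(seq_len(k), function(j) {
        w <- resp[, j]
        as.numeric((Matrix::t(altC) %*% w + a) /
                   (Matrix::t(depC) %*% w + 2 * a))
      }, numeric(ncol(altC)))
      ll <- vapply(seq_len(k), function(j) .binomLogLik(altC, depC, f[, j]),
                   numeric(nC))
      m <- apply(ll, 1, max)
      post <- exp(ll - m)
      tot <- rowSums(post)
      resp <- post / tot
      # EM objective: marginal log-likelihood plus the Beta log-prior; this
      # is the quantity EM provably never decreases
      fc <- pmin(pmax(f, 1e-6), 1 - 1e-6)
      totalLL <- sum(m + log(tot) - log(k)) +
        a * sum(log(fc) + log(1 - fc))
      if (totalLL < prevLL - 1e-6 * max(1, abs(prevLL)))
        stop("EM objective decreased: ", prevLL, " -> ", totalLL)
      trace <- c(trace, totalLL)
      if (totalLL - prevLL < tol && iter > 1) break
      prevLL <- totalLL
    }
    if (is.null(best) || totalLL > best$ll)
      best <- list(ll = totalLL, f = f, trace = trace)
  }
  f <- best$f
  # hypothesis set: k singlets + k(k-1)/2 doublets (averaged fractions)
  pairs <- if (k >= 2) combn(k, 2) else matrix(0, 2, 0)
  hyp <- cbind(f, (f[, pairs[1, ], drop = FALSE] +
                   f[, pairs[2, ], drop = FALSE]) / 2)
  hypNames <- c(as.character(seq_len(k)),
                paste0("doublet_", pairs[1, ], "_", pairs[2, ]))
  prior <- c(rep((1 - doubletPrior) / k, k),
             rep(doubletPrior / ncol(pairs), ncol(pairs)))
  llAll <- matrix(-Inf, n, length(hypNames),
                  dimnames = list(rownames(alt), hypNames))
  llC <- vapply(seq_len(ncol(hyp)),
                function(j) .binomLogLik(altC, depC, hyp[, j]), numeric(nC))
  llAll[covered, ] <- llC
  lp <- sweep(llC, 2, log(prior), "+")
  m <- apply(lp, 1, max)
  post <- exp(lp - m); post <- post / rowSums(post)
  label <- rep("unassigned", n)
  posterior <- rep(1 / length(hypNames), n)
  win <- max.col(post, ties.method = "first")
  lab <- hypNames[win]
  lab[win > k] <- "doublet"
  label[covered] <- lab
  posterior[covered] <- post[cbind(seq_len(nC), win)]
  new("GenotypeAssignment", barcode = rownames(alt), label = label,
      posterior = posterior, logLik = llAll, k = as.integer(k),
      logLikTrace = best$trace)
}

# Best label matching run B's clusters onto run A's by maximum overlap,
# searched over all permutations (k <= 8).
.matchClusters <- function(labA, labB, k) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  cls <- as.character(seq_len(k))
  singA <- labA %in% cls & labB %in% cls
  best <- cls; bestScore <- -1
  for (p in perms(cls)) {
    mapped <- setNames(p, cls)
    score <- sum(labA[singA] == mapped[labB[singA]])
    if (score > bestScore) { bestScore <- score; best <- mapped }
  }
  best
}

#' Consensus of two genotype-assignment runs
#'
#' Implements the dual-run retention rule: a nucleus is kept when both runs
#' agree on the same singlet cluster, or when exactly one run assigns it to a
#' cluster confidently (posterior >= `confidence`, singlet). Two confident
#' but conflicting singlet calls yield `"unassigned"`; any agreed or
#' confident doublet decision is excluded (label `"doublet"`). Cluster labels
#' of run B are first matched to run A by maximum overlap.
#'
#' @param runA,runB [GenotypeAssignment-class] objects over the same
#'   barcodes with the same `k`.
#' @param confidence posterior threshold defining a confident call.
#' @return a [GenotypeAssignment-class] holding the consensus; only nuclei
#'   with a cluster label are retained downstream.
#' @export
consensusAssign <- function(runA, runB, confidence = 0.99) {
  if (!identical(runA@barcode, runB@barcode))
    stop("runs must cover the same barcodes in the same order")
  stopifnot(runA@k == runB@k)
  k <- runA@k
  cls <- as.character(seq_len(k))
  mapped <- .matchClusters(runA@label, runB@label, k)
  labB <- runB@label
  labB[labB %in% cls] <- mapped[labB[labB %in% cls]]
  labA <- runA@label
  confA <- runA@posterior >= confidence & labA %in% cls
  confB <- runB@posterior >= confidence & labB %in% cls
  n <- length(labA)
  label <- rep("unassigned", n)
  posterior <- pmax(runA@posterior, runB@posterior)
  agreeSing <- labA == labB & labA %in% cls
  label[agreeSing] <- labA[agreeSing]
  onlyA <- !agreeSing & confA & !confB
  label[onlyA] <- labA[onlyA]
  onlyB <- !agreeSing & confB & !confA
  label[onlyB] <- labB[onlyB]
  conflict <- !agreeSing & confA & confB
  label[conflict] <- "unassigned"
  # doublet involvement in the retained decision excludes the nucleus
  agreeDoub <- labA == "doublet" & labB == "doublet"
  confDoubA <- labA == "doublet" & runA@posterior >= confidence & !confB
  confDoubB <- labB == "doublet" & runB@posterior >= confidence & !confA
  label[agreeDoub | confDoubA | confDoubB] <- "doublet"
  new("GenotypeAssignment", barcode = runA@barcode, label = label,
      posterior = posterior, logLik = runA@logLik, k = k,
      logLikTrace = numeric(0))
}

#' Match cluster labels to known truth by best permutation
#'
#' Utility for recovery tests: relabels an assignment's clusters to maximize
#' singlet agreement with a truth vector.
#'
#' @param assignment a [GenotypeAssignment-class].
#' @param truthGenotype integer/character truth per nucleus (singlets).
#' @return the assignment with relabeled clusters.
#' @export
matchToTruth <- function(assignment, truthGenotype) {
  k <- assignment@k
  mapped <- .matchClusters(as.character(truthGenotype), assignment@label, k)
  lab <- assignment@label
  cls <- as.character(seq_len(k))
  lab[lab %in% cls] <- mapped[lab[lab %in% cls]]
  assignment@label <- lab
  assignment
}
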