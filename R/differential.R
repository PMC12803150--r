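# Marker detection, condition DEG calling with the study's thresholds, and
# the negative-binomial time-course interaction test.

# Median-of-ratios size factors, positive-count variant (composition-robust;
# zeros excluded from each gene's geometric mean and from the per-cell
# ratio median, so sparse count matrices are handled).
.sizeFactors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- 0
  logGeo <- rowSums(lg) / ncol(counts)
  use <- rowSums(counts > 0) > 0.5 * ncol(counts)
  if (sum(use) >= 5) {
    sf <- vapply(seq_len(ncol(counts)), function(j) {
      x <- counts[use, j]
      pos <- x > 0
      if (!any(pos)) return(NA_real_)
      exp(median(log(x[pos]) - logGeo[use][pos]))
    }, numeric(1))
    if (all(is.finite(sf) & sf > 0)) return(sf / exp(mean(log(sf))))
  }
  tot <- pmax(colSums(counts), 1)
  tot / exp(mean(log(tot)))
}

#' One-vs-rest marker detection per cell type
#'
#' For each type, genes detected in at least `minPct` of its cells and with
#' positive log2 fold change strictly above `logfcMin` are tested one-vs-rest
#' by Wilcoxon rank-sum; Bonferroni correction is applied over the genes
#' tested within the type, and markers with adjusted p below `alpha` are
#' retained. Fold changes are log2 ratios of (de-logged mean + 1) values.
#'
#' @param norm an [AnnotatedCounts-class] with `logcounts`, or a normalized
#'   genes x cells matrix.
#' @param labels per-cell type labels (taken from `cell_type` when `norm` is
#'   an `AnnotatedCounts` and `labels` is NULL).
#' @param logfcMin strict lower bound on positive log2FC.
#' @param minPct minimum detection fraction in the focal type (inclusive).
#' @param alpha Bonferroni-adjusted p threshold.
#' @return data.frame (gene, group, log2FC, pct1, pct2, p, p_adj).
#' @export
findMarkers <- function(norm, labels = NULL, logfcMin = 0.25, minPct = 0.2,
                        alpha = 0.05) {
  if (is.null(labels) && is(norm, "AnnotatedCounts")) labels <- cellTypes(norm)
  m <- .asDense(.normMatrix(norm))
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m), length(unique(labels)) >= 2)
  out <- list()
  for (ct in sort(unique(labels))) {
    focal <- labels == ct
    if (sum(focal) < 3) {
      warning("type '", ct, "' has fewer than 3 cells; skipped")
      next
    }
    pct1 <- .pctExpressed(m, focal)
    pct2 <- .pctExpressed(m, !focal)
    lfc <- .log2FC(m, focal)
    tested <- which(pct1 >= minPct & lfc > logfcMin)
    if (!length(tested)) next
    rs <- .rankSumRows(m[tested, , drop = FALSE], focal)
    padj <- pmin(rs$p.two.sided * length(tested), 1)
    keep <- padj < alpha
    if (!any(keep)) next
    out[[ct]] <- data.frame(gene = rownames(m)[tested][keep], group = ct,
                            log2FC = lfc[tested][keep],
                            pct1 = pct1[tested][keep],
                            pct2 = pct2[tested][keep],
                            p = rs$p.two.sided[keep],
                            p_adj = padj[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(gene = character(), group = character(),
                                      log2FC = numeric(), pct1 = numeric(),
                                      pct2 = numeric(), p = numeric(),
                                      p_adj = numeric())
  rownames(res) <- NULL
  res
}

#' Condition differential expression within a cell type
#'
#' Two-sided rank-sum test per gene between plucked and control cells; the
#' DEG set is `{|log2FC| > logfcMin and p < alpha}` on the raw p-value, with
#' signs relative to the plucked (focal) group.
#'
#' @param norm normalized genes x cells matrix (or `AnnotatedCounts` with
#'   `logcounts`) already subset to one cell type.
#' @param condition per-cell condition labels with two levels.
#' @param focal the focal level (default `"plucked"` when present).
#' @param logfcMin strict absolute log2FC bound.
#' @param alpha raw p threshold (strict `<`).
#' @return data.frame (gene, log2FC, pct1, pct2, p, deg, direction).
#' @export
conditionDE <- function(norm, condition, focal = NULL, logfcMin = 0.25,
                        alpha = 0.05) {
  m <- .asDense(.normMatrix(norm))
  condition <- as.character(condition)
  lv <- unique(condition)
  if (length(lv) < 2) stop("both conditions must be present")
  stopifnot(length(lv) == 2, length(condition) == ncol(m))
  if (is.null(focal)) focal <- if ("plucked" %in% lv) "plucked" else lv[1]
  g1 <- condition == focal
  lfc <- .log2FC(m, g1)
  rs <- .rankSumRows(m, g1)
  deg <- abs(lfc) > logfcMin & rs$p.two.sided < alpha
  data.frame(gene = rownames(m) %||% as.character(seq_len(nrow(m))),
             log2FC = lfc, pct1 = .pctExpressed(m, g1),
             pct2 = .pctExpressed(m, !g1), p = rs$p.two.sided, deg = deg,
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
             row.names = NULL)
}

#' Negative-binomial time-course interaction test
#'
#' Fits, per gene, a negative-binomial regression of raw counts on
#' `condition * timepoint` (timepoint as a factor) plus a fixed `replicate`
#' covariate, with a log library-size offset. The gene-wise dispersion is
#' estimated by maximum likelihood on the full model, then the interaction
#' block is tested by a likelihood-ratio chi-square between the full and the
#' additive model refit at that dispersion. P-values are BH-adjusted. A
#' single-level replicate covariate is dropped automatically.
#'
#' @param counts raw integer genes x cells matrix, or an
#'   [AnnotatedCounts-class].
#' @param condition,timepoint,replicate per-cell design vectors (taken from
#'   `colData` when NULL and `counts` is an `AnnotatedCounts`).
#' @param alpha BH-adjusted significance threshold recorded in the output.
#' @return data.frame (gene, lrt, df, p, p_adj, theta, significant).
#' @export
timecourseTest <- function(counts, condition = NULL, timepoint = NULL,
                           replicate = NULL, alpha = 0.05) {
  if (is(counts, "AnnotatedCounts")) {
    cd <- colData(counts)
    condition <- condition %||% cd$condition
    timepoint <- timepoint %||% cd$timepoint
    replicate <- replicate %||% cd$individual
    counts <- as.matrix(SingleCellExperiment::counts(counts))
  }
  counts <- as.matrix(counts)
  if (any(counts != round(counts))) stop("counts must be integers")
  stopifnot(!is.null(condition), !is.null(timepoint))
  condition <- factor(condition)
  timepoint <- factor(timepoint)
  stopifnot(nlevels(condition) == 2, nlevels(timepoint) >= 2)
  useRep <- !is.null(replicate) && length(unique(replicate)) > 1
  off <- log(.sizeFactors(counts))
  df <- data.frame(condition = condition, timepoint = timepoint, off = off)
  if (useRep) df$replicate <- factor(replicate)
  fullForm <- if (useRep) y ~ condition * timepoint + replicate + offset(off)
              else y ~ condition * timepoint + offset(off)
  redForm <- if (useRep) y ~ condition + timepoint + replicate + offset(off)
             else y ~ condition + timepoint + offset(off)
  res <- lapply(seq_len(nrow(counts)), function(g) {
    df$y <- counts[g, ]
    if (var(df$y) == 0)
      return(data.frame(lrt = NA_real_, df = NA_real_, p = NA_real_,
                        theta = NA_real_))
    fitFull <- tryCatch(
      suppressWarnings(glm.nb(fullForm, data = df)),
      error = function(e) NULL)
    if (is.null(fitFull))
      return(data.frame(lrt = NA_real_, df = NA_real_, p = NA_real_,
                        theta = NA_real_))
    theta <- fitFull$theta
    fam <- negative.binomial(theta)
    f1 <- suppressWarnings(glm(fullForm, family = fam, data = df))
    f0 <- suppressWarnings(glm(redForm, family = fam, data = df))
    lrt <- as.numeric(deviance(f0) - deviance(f1))
    dfr <- df.residual(f0) - df.residual(f1)
    data.frame(lrt = lrt, df = dfr,
               p = pchisq(lrt, dfr, lower.tail = FALSE), theta = theta)
  })
  res <- do.call(rbind, res)
  res <- cbind(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
               res)
  res$p_adj <- NA_real_
  ok <- !is.na(res$p)
  res$p_adj[ok] <- p.adjust(res$p[ok], method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  rownames(res) <- NULL
  res
}
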