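# Pulse-chase tooth classification, tooth-gain statistics, and the paired
# and between-species tests of the plucking experiment.

#' Classify teeth from dual vital-dye labels
#'
#' Alizarin (pulse) marks mineralized tissue present before plucking;
#' Calcein (chase) marks tissue mineralizing afterwards. Teeth positive for
#' both dyes are pre-existing (`old`), Calcein-only teeth formed during the
#' chase (`new`), unlabeled teeth are `unlabeled`, and Alizarin-only teeth
#' (pulse-labeled but not chase-labeled) are `anomalous` and excluded from
#' gain computations.
#'
#' @param table a `ToothTable` data.frame with logical `alizarin` and
#'   `calcein` columns.
#' @return the table with a `status` column.
#' @export
classifyTeeth <- function(table) {
  stopifnot(all(c("alizarin", "calcein") %in% colnames(table)))
  bad <- which(is.na(table$alizarin) | is.na(table$calcein))
  if (length(bad))
    stop("missing dye labels in rows: ", paste(head(bad, 5), collapse = ", "))
  a <- table$alizarin; c <- table$calcein
  table$status <- ifelse(a & c, "old",
                  ifelse(!a & c, "new",
                  ifelse(!a & !c, "unlabeled", "anomalous")))
  table
}

#' Tooth gain per jaw quadrant
#'
#' Gain is the number of new teeth divided by the countable total
#' (new + old) per quadrant. `unlabeled` and `anomalous` teeth enter neither
#' numerator nor denominator (they are reported in QC columns). The fish-level
#' side value is the unweighted mean over that side's quadrants.
#'
#' @param classified output of [classifyTeeth()], with `fish`, `species`,
#'   `side`, `quadrant` columns.
#' @return list with `quadrants` (per-quadrant gains and QC counts) and
#'   `fishSides` (fish x side mean gains, with species).
#' @export
toothGain <- function(classified) {
  stopifnot("status" %in% colnames(classified))
  qs <- unique(classified[, c("fish", "species", "side", "quadrant")])
  rows <- lapply(seq_len(nrow(qs)), function(i) {
    q <- classified[classified$quadrant == qs$quadrant[i], ]
    nNew <- sum(q$status == "new"); nOld <- sum(q$status == "old")
    data.frame(qs[i, ], new = nNew, old = nOld,
               unlabeled = sum(q$status == "unlabeled"),
               anomalous = sum(q$status == "anomalous"),
               gain = if (nNew + nOld > 0) nNew / (nNew + nOld) else NA_real_)
  })
  quad <- do.call(rbind, rows)
  rownames(quad) <- NULL
  empty <- is.na(quad$gain)
  if (any(empty))
    warning(sum(empty), " quadrant(s) with no countable teeth skipped")
  ok <- quad[!empty, ]
  agg <- aggregate(gain ~ fish + species + side, data = ok, FUN = mean)
  list(quadrants = quad, fishSides = agg)
}

#' Paired test of plucked vs control tooth gain
#'
#' Two-sided paired Student's t-test on the per-fish difference
#' (plucked minus control) of side-mean gains. A zero-variance nonzero
#' difference is reported as degenerate (t infinite, p 0) rather than
#' crashing.
#'
#' @param fishSides data.frame from [toothGain()] (`fish`, `side`, `gain`).
#' @return list with `t`, `df`, `p`, `meanDiff`, `n`, `degenerate`.
#' @export
pairedToothTest <- function(fishSides) {
  w <- reshape(fishSides[, c("fish", "side", "gain")], idvar = "fish",
               timevar = "side", direction = "wide")
  w <- w[complete.cases(w), ]
  if (nrow(w) < 2) stop("need at least 2 fish with both sides")
  d <- w$gain.plucked - w$gain.control
  n <- length(d)
  if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-10)
      return(list(t = 0, df = n - 1, p = 1, meanDiff = 0, n = n,
                  degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                meanDiff = mean(d), n = n, degenerate = TRUE))
  }
  tt <- t.test(w$gain.plucked, w$gain.control, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = unname(tt$estimate), n = n,
       degenerate = FALSE)
}

#' Between-species one-way ANOVA with Tukey-Kramer contrasts
#'
#' One-way ANOVA of per-fish plucked-side gains across species, followed by
#' Tukey's honest significant differences (the Tukey-Kramer studentized
#' range procedure, valid for unequal group sizes).
#'
#' @param fishSides data.frame from [toothGain()]; only `side == "plucked"`
#'   rows are used (pass a pre-filtered frame to test another side).
#' @param side side analyzed, default `"plucked"`.
#' @return list with `F`, `df` (c(between, within)), `p`, and `tukey`
#'   (data.frame contrast, diff, lwr, upr, p_adj).
#' @export
speciesANOVA <- function(fishSides, side = "plucked") {
  d <- fishSides[fishSides$side == side, ]
  d$species <- factor(d$species)
  if (nlevels(d$species) < 2) stop("need at least 2 species")
  if (any(table(d$species) < 2)) stop("need at least 2 fish per species")
  fit <- aov(gain ~ species, data = d)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$species
  list(F = s$`F value`[1], df = s$Df, p = s$`Pr(>F)`[1],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}
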