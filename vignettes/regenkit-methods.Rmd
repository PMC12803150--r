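---
title: "regenkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regenkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenkit)
```

# Scope

Polyphyodont fish replace every tooth throughout life. `regenkit` implements
the quantitative core of a tooth-plucking pulse-chase paradigm studied with
single-nucleus RNA-seq: dye-based quantification of replacement tempo,
barcode quality control and embedding, genetic demultiplexing of pooled
nuclei, cross-species cell-type homology scoring, developmental-potential
vector fields and trajectory-gene testing, condition and time-course
differential expression, and differential ligand-receptor communication
networks. Every stage can be driven by the package's own synthetic
generators, which plant known structure so that recovery is checkable.

This vignette records the models, their assumptions, the tunable parameters,
and the design decisions taken where the methodology was genuinely open.

# Pulse-chase tooth gain

Fish are pulsed with Alizarin (marks mineralized tissue present at the start),
teeth are plucked from one side of each jaw, and after the chase interval the
fish are labeled with Calcein (marks newly mineralizing tissue). A tooth
positive for both dyes predates the experiment (`old`); a Calcein-only tooth
formed during the chase (`new`). Tooth gain for a jaw quadrant is

$$g = \frac{\#\text{new}}{\#\text{new} + \#\text{old}},$$

the fish-level side value is the unweighted mean over that side's quadrants,
and the side contrast is a two-sided paired Student's t-test on the per-fish
difference (plucked − control). Between-species comparison of plucked-side
gains uses one-way ANOVA with Tukey-Kramer contrasts (valid under unequal
group sizes; `stats::TukeyHSD` implements the studentized-range procedure).

Two label patterns are not covered by the dye logic: unlabeled teeth
(`A−C−`) and Alizarin-only teeth (`A+C−`, pulse-labeled but not
chase-labeled). Both are excluded from numerator and denominator and counted
in QC columns; Alizarin-only teeth are flagged `anomalous` because a
mineralized tooth should continue to take up Calcein during the chase. A
zero-variance set of paired differences is reported as degenerate (t
infinite, p of 0 with a `degenerate` flag) rather than crashing.

The generator defaults encode the study design: three species with 8, 8 and
9 fish, two jaws × two sides per fish, and a plucked-side per-tooth
replacement probability of 0.60 against a 0.17 baseline — about 3.5-fold,
so roughly 60% of plucked-side teeth are new at the end of the chase. Teeth
per quadrant defaults to 12, a realistic count for the anterolateral region
scored in such experiments.

# Barcode QC and embedding

`filterBarcodes()` retains a barcode when 250 ≤ genes detected ≤ 2,500 and
the mitochondrial count fraction is at most 5%. "Genes detected" means genes
with count > 0; the mitochondrial fraction is computed on raw counts. All
three bounds are inclusive on the retained side: a barcode at exactly 2,500
genes or exactly 5% mitochondrial content is kept, matching rules phrased as
"fewer than" and "more than". The per-barcode decision log (barcode, genes,
mito fraction, kept, reason) is stored in the object's metadata.

`logNormalize()` uses counts-per-10,000 with natural `log1p` — the
convention of the mainstream single-cell toolkits. `selectHVG()` is a
mean.var.plot-style selector: genes are placed into 20 equal-frequency bins
of mean expression, the dispersion (variance/mean of the normalized values)
is z-scored within each bin, and the top genes by standardized dispersion
are returned (ties break by gene order, so the choice is deterministic and
invariant to cell order). Because standardization is within-bin, the scores
are only comparable when truly variable genes are a minority spread across
bins — the situation in real data; for tiny gene panels the bin count should
be reduced (`nBins`).

`embedPCA()` keeps up to 50 components with a deterministic sign convention
(largest-magnitude loading positive). `buildKNN()` computes exact Euclidean
k = 50 nearest neighbors (ties broken by cell index, self excluded),
blockwise so memory stays linear in the block size. Covariate regression of
mitochondrial percentage and UMI count before scaling — sometimes applied to
real data — is out of scope here; downstream checks use synthetic data where
those covariates are not confounded.

# Pooled-genotype deconvolution

Nuclei pooled from 2-4 individuals are demultiplexed from the variant
evidence in their reads. For nucleus $n$ and variant $v$ with $a_{nv}$
alternate and $r_{nv}$ reference reads, cluster $k$ with alt-allele fraction
$f_{kv}$ has binomial log-likelihood
$\sum_v a_{nv}\log f_{kv} + r_{nv}\log(1-f_{kv})$. EM alternates soft
assignment with a MAP update of $f$ under a Beta(1/2, 1/2) prior; the
penalized EM objective (marginal log-likelihood plus log-prior) is asserted
non-decreasing at every iteration, and the best of `nRestarts` random
restarts is kept. After convergence each nucleus is scored under the K
singlet hypotheses plus one doublet hypothesis per cluster pair (allele
fractions averaged — a two-genotype droplet contributes reads from both
genomes equally), with a configurable doublet prior (default 0.05). Nuclei
with zero variant coverage are `unassigned`, not an error. Cluster labels
are arbitrary up to permutation; `matchToTruth()` relabels against a known
truth for recovery tests.

`consensusAssign()` implements the dual-run retention rule: keep a nucleus
when both runs agree on a singlet cluster, or when exactly one run is
confident (posterior ≥ 0.99, singlet). Two confident but conflicting singlet
calls are conservatively dropped — retaining "either" would be
nondeterministic. Agreed or confidently-called doublets are excluded from
the final set. In the original design the two runs differ by read
base-quality threshold; here any two assignments over the same barcodes
qualify (e.g. two EM seeds), since the consensus logic is agnostic to what
distinguished the runs.

# Cross-species homology scoring

A weighted homology table (geneA, geneB, weight ∈ (0,1]) drives a joint
embedding: expression of dataset B is projected into A's gene space with
each A gene the weight-normalized mean of its B partners, so higher-weight
homologs influence the integration more and uniform weight rescaling
cancels; the concatenated matrices are jointly log-normalized and
PCA-embedded. This deliberately replaces the iterative expression-weighted
graph refinement of full cross-species integration pipelines: the statistic
and its null — the reusable contribution — operate on any cross-dataset kNN
graph.

The similarity score is
$$S(a, b) = \frac{1}{|B_b|} \sum_{j \in B_b} \#\{\text{type-}a\text{ A cells among } j\text{'s } k \text{ cross-dataset neighbors}\},$$
the average neighbor count in the B→A direction; a symmetrized mean of the
two directions is available behind `direction = "symmetric"`. Neighbor
counts partition k, so the columns of S sum to k.

Significance uses a permutation null: both label vectors are shuffled
independently (preserving type frequencies) `nPerm` times, and a pair is
significant only when its observed score **strictly exceeds every** permuted
score. The default compares each pair against its own permutation
distribution (`null = "pair"`); a stricter reading — exceed the maximum
permuted score across the whole column of the B type — is available as
`null = "rowmax"`. Empirical p-values are $(1 + \#\{perm \ge obs\})/(n+1)$,
never zero.

# Developmental potential and directed transitions

The potential score rests on one assumption: naive cells express more genes
than mature cells. The detected-gene count per cell is rank-scaled to
[0, 1], smoothed by `m = 3` rounds of graph diffusion
$c \leftarrow (1-\alpha)\,\tilde g + \alpha\, \bar A c$ with $\alpha = 0.5$
and the row-normalized kNN adjacency $\bar A$, then rank-scaled again
(ties share a mid-rank value; non-constant scores always span [0, 1]). The
full published potential method additionally refines a gene signature and
smooths by non-negative least squares; those refinements are omitted because
every downstream use here is ordinal — root identification and transition
direction — which the detected-gene count plus diffusion preserves, and the
lineage-recovery tests check exactly that ordinal property.

The directed kernel sets, for each kNN edge $i \to j$,
$$T_{ij} \propto \exp\!\big(\beta\,(t_j - t_i)\big), \qquad t = 1 - c,$$
row-normalized, with $\beta = 10$ by default; $\beta = 0$ recovers the
unbiased row-normalized graph, and isolated rows receive a self-loop. The
vector field is the expected embedding step
$\delta_i = \sum_j T_{ij}(x_j - x_i)$.

One geometric caveat: the kernel can only point "forward" where a cell's
neighborhood actually spans cells later in pseudotime. With k = 50
neighbors, differentiation stages wider than k cells leave most
neighborhoods stage-internal, where score differences are noise; the
synthetic lineage default (5 stages × 20 cells, nested expressed-gene sets
so stages overlap) keeps stage width below k. On real data the same logic
argues for k of the order of the local stage population, which the study's
k = 50 satisfies for its progenitor domains.

`moranTest()` computes per-gene Moran's I on the symmetrized binary kNN
adjacency,
$$I = \frac{n}{W} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},$$
with the analytic normal approximation against $E[I] = -1/(n-1)$
(one-sided: positive autocorrelation is what marks trajectory genes) and BH
correction. Constant genes are flagged and excluded. Trajectory genes are
those with q < 0.01, then the top 300 by I. The principal-graph machinery
that a full trajectory pipeline would fit first is out of scope; the kNN
graph stands in as the neighborhood structure, which changes the weights but
not the statistic.

# Differential expression

Group tests are Wilcoxon rank-sum, vectorized over genes with the
tie-corrected normal approximation (cross-checked against
`stats::wilcox.test` in the tests). Fold changes follow the single-cell
convention $\log_2\big((\bar u_1 + 1)/(\bar u_2 + 1)\big)$ on de-logged
(counts-per-scale) means, so the printed 0.25 threshold is well defined.

* `findMarkers()`: one-vs-rest, positive direction only, tested where the
  focal detection fraction is ≥ 0.2 and log2FC strictly exceeds 0.25,
  Bonferroni-corrected over the genes tested within the type.
* `conditionDE()`: two-sided within a cell type; a DEG satisfies
  |log2FC| > 0.25 and raw p < 0.05, both strict, signs relative to plucked.
  The asymmetry with the marker test (Bonferroni there, raw p here) is kept
  deliberately, each rule as stated for its use.
* `timecourseTest()`: per-gene negative-binomial regression of raw counts on
  `condition * timepoint` (timepoint as factor) with a log size-factor
  offset; the interaction block is tested by likelihood ratio between the
  full and additive models refit at the full model's ML dispersion, BH
  across genes. The random intercept of a mixed-effects formulation is
  simplified to a fixed replicate covariate (dropped automatically when only
  one replicate level exists) — with the handful of replicates typical of
  pooled designs a fixed effect absorbs the same variance without the
  fitting fragility. Size factors are positive-count median-of-ratios
  (composition-robust; plain library-size offsets let strong planted effects
  bleed into null genes).

# Cell-cell communication

For interaction $i$ with ligand level $L_s$ in sender $s$ and receptor
level $R_r$ in receiver $r$ (per-type trimmed means, 10% per tail; multi-
subunit complexes via geometric mean over subunits, zero if any subunit is
absent), the communication probability follows mass action with Hill
saturation:
$$P_{sri} = \frac{E}{K_h + E}, \qquad
  E = L_s R_r \,\frac{1 + AG}{1 + ANT},$$
with $K_h = 0.5$ and $AG, ANT$ Hill-transformed cofactor levels. Folding the
cofactor modulation into the mass-action term *before* saturation (rather
than scaling the saturated probability) keeps $P \in [0, 1)$ for any
cofactor strength; without cofactors $L R = K_h$ gives exactly $P = 0.5$.
Significance is a cell-label permutation test (default 100 shuffles, p =
fraction of permuted tensors ≥ observed), and probabilities with p ≥ 0.05
are set to zero **before** every aggregation, so only statistically
supported links enter pathway flows, centralities and differentials.

Pathway probability is the sum of significant interaction probabilities
within the pathway; outgoing/incoming centrality is the tensor mass summed
over the other two axes (the two centralities both sum to the total mass —
an identity asserted to 1e-9 in the tests). Differential comparisons are
always plucked − control, per timepoint: an interaction-strength matrix over
(sender, receiver), per-type centrality deltas, and per-pair pathway
rankings by absolute flow difference with condition-exclusive pathways
flagged. A count-based differential (numbers of significant interactions)
accompanies the summed-strength matrix, since either convention is found in
practice. PPI-network smoothing of expression before inference requires an
external protein-protein interaction resource and is omitted.

The shipped toy database (`inst/extdata/lr_toy_db.tsv`) has 30 interactions
in 7 pathways named for signaling families prominent in dental regeneration
(Collagen, MMP, Slit-Robo, SPP1, Semaphorin, Notch, BMP); all gene symbols
are synthetic.

# Synthetic data: what it emulates, what it does not

Counts are gamma-Poisson: mean $\mu$, variance $\mu + \mu^2/r$ with
dispersion $r$ shared across genes — recovery tests need planted ordering,
not per-gene dispersion realism. The atlas generator plants disjoint
marker-gene programs (default 25 types, enrichment $e^{1.5}$), a dedicated
mitochondrial block whose expected count share is controllable, and fixed
library-size expectation; rates are not renormalized per type, so a program
gene's mean ratio between its own and other types is exactly
$e^{\text{programLogfc}}$. The species-pair generator shares programs
between planted homologous types through a 1:1 weighted gene map; private
types get programs on species-private gene blocks. The pool generator draws
genotypes from {0, ½, 1} alt fractions with ≥ 20% pairwise discordance,
Poisson depth, binomial allele sampling with error flips, and equal-weight
two-genotype doublets. The LR time-course resamples atlas type means over
conditions × timepoints {0, 1, 3, 7}, multiplying planted ligand genes in
the sender and receptor genes in the receiver by the condition effect only
in plucked cells at affected timepoints, with a mild lognormal replicate
effect. `baselineModerateGenes()` picks background genes in the
moderate-baseline regime where a few-fold induction converts a
non-significant interaction into a strong one — the injury-induced
signaling case the study design targets.

Not emulated: read-level artifacts (FASTQ/BAM), ambient RNA, batch effects,
doublet *transcriptomes* in expression matrices (doublets exist only in the
genotype model), per-gene dispersion variation, and the cluster-level
annotation judgment that produced the real study's cell-type alphabet.
Passing recovery tests therefore demonstrates correctness of the statistics
and their calibration under the stated generative model, not robustness to
every artifact of real tissue.

# Numerical choices and problem sizes

All randomness flows through explicit integer seeds; every generator is
bit-reproducible. Rank scaling uses average ties; kNN ties break by cell
index; HVG ties by gene order; EM convergence is 1e-6 on the objective with
200 iteration cap; permutation p-values use the +1 convention. Degenerate
inputs (all-constant embedding input, zero-coverage nuclei, zero-variance
paired differences, single-condition cell types, single-level replicate)
take documented non-crashing paths.

The test and acceptance workloads run on one CPU in a few minutes at sizes
chosen to keep Monte-Carlo error comfortably inside the asserted margins:
pools of 3 × 300 nuclei × 200 variants at depth 5; species pairs of
4 × 60 cells × 600 genes; lineages of 100 cells × 1,000 genes at k = 50;
time-course designs of 800 cells × 500 genes; twenty seeded communication
simulations of 4 × 240 cells; one hundred pulse-chase replicates of the
25-fish design.
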