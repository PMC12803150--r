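# regenkit

Quantitative toolkit for studies of whole-tooth regeneration in
polyphyodont fish. Cichlids replace every tooth one-for-one throughout
life; plucking a tooth accelerates replacement on the plucked side, and
single-nucleus RNA-seq of plucked versus control jaw tissue across a
time course reveals the cell populations and signals involved. `regenkit`
implements the analysis core of that paradigm as tested, reusable R
functions, together with synthetic-data generators that plant known ground
truth so every stage is verifiable offline.

## What it computes

* **Pulse-chase tooth gain** — teeth labeled by Alizarin (pulse) and
  Calcein (chase) are classified old/new; tooth gain per jaw quadrant is
  g = #new / (#new + #old); plucked vs control sides are compared by a
  paired Student's t-test and species by one-way ANOVA with Tukey-Kramer
  contrasts.
* **Barcode QC and embedding** — retain barcodes with 250 ≤ genes detected
  ≤ 2,500 and mitochondrial fraction ≤ 5%; log-normalization (CP10K),
  binned-dispersion HVG selection (4,000 genes), 50-component PCA, exact
  k = 50 nearest-neighbor graph.
* **Pooled-genotype deconvolution** — a binomial-mixture EM over
  per-variant alt-allele fractions f_kv assigns nuclei from 2-4-individual
  pools, with doublet hypotheses (averaged fractions per cluster pair) and
  a dual-run consensus retention rule.
* **Cross-species homology scores** — on a homology-weighted joint
  embedding, S(a, b) is the average number of type-a cells of species A
  among the k cross-species neighbors of species-B cells of type b; pairs
  are significant only when the observed score strictly exceeds all
  label-permutation scores.
* **Developmental potential and vector fields** — a gene-count potential
  score c ∈ [0, 1] (naive cells express more genes), a directed transition
  kernel T_ij ∝ exp(β (t_j − t_i)) with pseudotime t = 1 − c, and
  per-gene Moran's I trajectory testing (q < 0.01, top 300 by I).
* **Differential expression** — Wilcoxon markers (min.pct 0.2, log2FC >
  0.25, Bonferroni), condition DEGs (|log2FC| > 0.25 and p < 0.05), and a
  negative-binomial `condition * timepoint` interaction test with BH
  correction.
* **Cell-cell communication** — mass-action/Hill probabilities
  P = LR / (K_h + LR) per (sender, receiver, interaction) with
  permutation significance, pathway flows, in/out centralities, and
  plucked − control differential networks.

## Worked example

Simulate the pulse-chase design (3 species, 8/8/9 fish, plucked-side
replacement ≈ 3.5× baseline), quantify tooth gain, and run the study's
two tests:

```r
library(regenkit)
tab <- generatePulseChase(pulseChaseConfig(seed = 1))
tg  <- toothGain(classifyTeeth(tab))
head(tg$fishSides, 4)
#>    fish species    side      gain
#> 1 CA_f1      CA control 0.2083333
#> 2 CA_f2      CA control 0.2916667
#> 3 CA_f3      CA control 0.2083333
#> 4 CA_f4      CA control 0.2916667

pairedToothTest(tg$fishSides)
#> paired t = 18.24, df = 24, p = 1.43e-15, mean gain difference = 0.422

speciesANOVA(tg$fishSides)
#> species ANOVA: F(2,22) = 0.02, p = 0.979
```

The paired test detects the plucked-side acceleration decisively while the
between-species ANOVA finds no difference — replacement is faster after
plucking, with similar tempo across species.

Demultiplexing a synthetic 3-genotype pool (900 nuclei, 200 variants,
mean depth 5, 1% error, 5% doublets) with the dual-run consensus:

```r
pool <- generatePools(poolConfig(seed = 1))
runA <- clusterGenotypes(pool$data, k = 3, seed = 1)
runB <- clusterGenotypes(pool$data, k = 3, seed = 2)
cons <- matchToTruth(consensusAssign(runA, runB), pool$truth$genotype)
table(assignmentLabels(cons))
#>       1       2       3 doublet
#>     277     281     282      60
# singlet accuracy 1.000, doublet recall 1.000 against the planted truth
```

The methods vignette (`vignettes/regenkit-methods.Rmd`) documents every
model, parameter and design decision.

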