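---
title: "spermdyn: models, synthetic world and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spermdyn: models, synthetic world and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each
statistic assumes, what the synthetic generator plants and does not
plant, which defaults come from the published analysis the package
reimplements, and where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The pipeline and its statistics

### Empty-droplet recovery

Early meiotic (leptotene/zygotene) spermatocytes are transcriptionally
quiescent; a total-count filter discards them together with empty
droplets. The recovery test treats each barcode's counts $y$ as a
multinomial draw of its total $T$ from the ambient proportions $p$ and
uses the log-likelihood

$$\ell(y) = \log T! + \sum_g \left( y_g \log p_g - \log y_g! \right)$$

as the test statistic. Deviations from ambient composition push $\ell$
*down*, so the Monte-Carlo p-value is the lower-tail fraction among
`n_mc` simulated same-total draws, with the $(r+1)/(n_{mc}+1)$
estimator so p stays positive (a valid BH input). Barcodes are called
cells at BH FDR 1% (the published threshold). Two supporting rules:

* **Ambient profile.** Pooled counts of all barcodes with total
  $\le T = 100$, plus a pseudo-count $\alpha = 0.1$, renormalised. The
  published method delegates these constants to its tooling; both are
  exposed in `estimate_ambient()` and recorded with the profile.
* **Knee retention.** Barcodes above the knee of the log-rank/log-total
  curve are always retained. The knee is the minimum of the first
  derivative of a smoothing spline through the unique-total curve, with
  the search restricted to the interior of the rank range so boundary
  wiggles cannot win. This is deterministic and testable on monotone
  curves.

The Monte-Carlo simulation shares likelihood paths across totals: one
simulated path of cumulative draws yields $\ell$ at every observed total
(the increment for one more read of gene $g$ at step $t$ is
$\log t + \log p_g - \log(\text{count}_g)$), so 2000 iterations cover a
whole experiment in seconds.

### Normalisation

Size factors are cluster-pooled median ratios: cells are pre-clustered
(k-means on a PCA of library-normalised log counts, clusters capped at
2000 cells, the published cap), each cell's factor is the median ratio
to the cluster's average-cell reference over genes detected in at least
half the cluster, clusters are rescaled through their pseudo-bulk
median ratios, and factors are scaled to mean 1. The cited
deconvolution estimator is replaced deliberately (a spec-level design
decision): the contract the rest of the pipeline needs — exact recovery
of relative depth under no differential expression — is what the tests
assert (Pearson r ≥ 0.99 on a planted no-DE fixture). Very shallow
cells can be zero at over half the reference genes, which makes the
median ratio zero; the factor then falls back to the mean ratio, which
has the same no-DE expectation and is never zero for a cell with any
counts. Expression is `log2(count/sf + 1)`, so zeros stay zero and the
matrix stays sparse.

### Highly variable genes, PCA, clustering

The per-gene variance of log expression is decomposed against a loess
mean–variance trend (quadratic fallback below 200 genes); the
biological component is total minus trend and the top 1000 genes are
kept, ties broken by higher mean. PCA is centred with a deterministic
sign convention (largest-magnitude loading positive). Clustering
builds a k-nearest-neighbour graph on the leading 50 components,
weights edges by shared-neighbour ranks (weight $k - r/2$ with $r$ the
smallest rank sum of any shared neighbour, the cells themselves at
rank 0) and partitions by multi-level modularity optimisation
(`igraph::cluster_louvain`, an established routine, per the module
contract). k defaults to 5 with 10 and 15 as the published
alternatives.

### Principal-curve pseudotime

The fitter is the classic projection–smoothing iteration: order cells
by the current pseudotime, smooth every coordinate against that order
with a fixed-span running mean (span 0.1), project each cell to its
nearest curve point, and take arc-length position as the new
pseudotime, until the mean squared projection distance changes by less
than 1e-4 or 50 iterations. **Initialisation is the one deliberate
deviation from the stated design.** Initialising with PC1 leaves a
strongly curved six-stage trajectory folded (Spearman rho ≈ 0.36
against planted pseudotime on the default fixture), while the same
iteration started from a reasonable ordering converges to rho ≈ 0.998 —
the failure is the initialiser, not the fitter. The default initial
ordering is therefore distance along the minimum spanning tree of
k-means cluster centres, measured from one end of the tree diameter
(the approach popularised by cluster-based trajectory tools), computed
with a fixed internal seed; `init = "pc1"` restores the plain
initialisation. Orientation follows a caller-supplied early cell set;
reversal maps position $p$ to $L - p$ exactly.

### Markers, staging bridge

Marker detection runs a Welch t-test per gene for every ordered cluster
pair within each block (batch), combines per-block p-values by
weighted Stouffer and per-block effects by cell-count weighting,
combines across opposing clusters with Simes, and keeps the smallest
per-pair rank as the shortlist statistic. All p-value arithmetic is in
log space: planted markers are strong enough that double-precision p
underflows, and the top-50 shortlist needs the ordering to survive
that. A marker must have a positive effect against *every* other
cluster and BH FDR < 0.1 (the published rule).

The staging bridge Z-scores the top-50 panel per gene, fits a
probabilistic multiclass classifier on a seeded 2000-cell training
split, reports held-out accuracy, and classifies bulk samples from the
Z-scores of their log2 CPM. The published analysis used a random
forest; no random-forest package exists in this build environment, and
the component is explicitly interchangeable behind the probability
contract, so the default is a diagonal-covariance Gaussian classifier
(diagonal LDA, the nearest-shrunken-centroid family): deterministic,
probabilistic, and well behaved when the marker panel outnumbers the
training cells — regimes where iterative multinomial fitters proved
fragile. Bulk Z-scores are computed across the bulk
series itself — the literal reading of the published Methods — with
`project = TRUE` available to reuse the training cells' means and
standard deviations instead.

### X:A ratio, correlation screen, escape genes

The X:A ratio uses normalised, non-log expression (ratios of log values
would not be scale-free); a log-scale variant exists for sensitivity.
The expressed filter is strict `>` 30% detection in either reference
group, and the ratio is invariant to any per-cell rescaling, so the
choice of size factors cannot move it.

The complexity screen excludes genes with mean log expression ≤ 0.1,
computes Spearman rho against the number of genes detected, and
compares with an empirical null: each of `n_null` draws correlates a
random permutation of the complexity ranks with a randomly chosen
gene's ranks, so the pooled p-values are uniform under the global null
by construction. p is the two-sided tail with the $(r+1)/(n+1)$
estimator; classification is rho beyond ±0.3 at BH FDR < 0.1 (the
published rule). The published null size is 100,000; the tests use
10,000 to stay inside CI budgets, which the criterion itself sanctions.

The escape caller restricts to X genes with average counts ≥ 10, splits
the bulk series at postnatal day 20 (the boundary day counts as late —
the published text is inconsistent on this, so the split day is a
parameter), and runs the TREAT-style threshold test: group means on
the median-of-ratios normalised scale, pseudo-count 0.5, per-gene
method-of-moments dispersion shrunk toward a loess mean–dispersion
trend with prior weight 10, and Wald p re-centred at the nearer
boundary,

$$p = \Phi\!\left(-\frac{|\hat\beta| - \tau}{se}\right) +
      \Phi\!\left(-\frac{|\hat\beta| + \tau}{se}\right),$$

which reduces algebraically to the two-sided Wald test at $\tau = 0$
and is monotone non-decreasing in $\tau$. Calls require log2FC > 5 at
FDR < 10% with $\tau = 2$ (all published values).

### Proportions

Cell-type proportion shifts are tested per type with binomial logistic
regression of (count, total − count) on the group, the dispersion from
Pearson residuals. With three and four samples per group — the
published design — a per-type dispersion estimate makes the test
essentially powerless, while the published tooling moderates dispersion
across features; the dispersions are therefore shrunk across types with
`limma::squeezeVar` (the canonical empirical-Bayes moderation), floored
at 1, and the t reference gains the earned prior df.
`moderate = FALSE` restores the plain per-type estimator.

### Chromatin

Fragments are filtered in the published order: duplicates (identical
interval within a replicate), quality < 10, length > 1000 bp (exactly
1000 is kept — the rule removed pairs mapped *more than* 1000 bp
apart), then ≥ 1 bp blacklist overlap. A fragment counts in every
region it overlaps by ≥ 1 bp, matching window multi-counting in the
published tooling; a midpoint-assignment mode is provided. CPM is
count × 1e6 / library size; FPKM additionally divides by region length
in kb; promoters are [TSS − 2000, TSS + 200) by strand (the annotation
tooling's default, configurable). Promoter-set comparisons average CPM
across replicates, then use the rank-sum test — exact via the
closed-form null distribution when both sets have ≤ 12 promoters and
no ties, otherwise the normal approximation with tie-corrected
variance and continuity correction (a statistic exactly at its null
mean reports p = 1). High-signal regions merge the top 1000 windows
with a 1500-bp tolerance, ties broken by genomic order so the output
is independent of input order. Repeat enrichment is base-level: each
family's bases are collapsed first (a base counts once per family;
families are counted independently, the one point the published text
leaves open), the 2×2 table is bases in/out of regions × family/other,
the reported odds ratio is the sample odds ratio and p comes from
Fisher's exact test, with simple/telomeric/centromeric families
excluded first.

## 2. The synthetic world

`sim_config()` states the world once; everything downstream is a
deterministic function of it and the seed (bit-identical reruns are an
acceptance criterion). The defaults:

* **2000 genes** on three autosomes plus X (150), Y (50) and 13
  mitochondrial genes; 500 cells per stage across SG, LZ, P, D, RS,
  ES; 5000 empty droplets. Genes sit on an 8-kb grid so the 2.2-kb
  promoters of neighbouring genes cannot overlap (planted promoter
  fragments must not leak into a neighbour's window).
* **Programmes.** Each gene has a log-normal baseline (log2 sd 1.5).
  Each stage activates `n_on` genes (the complexity target; LZ's 500
  against D's 1400 plants the early-meiosis dip, ES's 450 the
  post-step-7 decline, reinforced by library sizes 1200 and 1500
  against 4000–6000 elsewhere). Genes outside a stage's programme keep
  15% of their baseline — soft attenuation, so complexity differences
  come from detection rates while the planted markers stay the
  strongest stage-specific signal. Fifty markers per stage get a
  16-fold boost and a well-expressed baseline (canonical markers are
  strong genes); the first-stage markers carry the published SSC and
  progenitor panel symbols so the stemness scores find their genes.
* **Continuity.** Cell programmes interpolate linearly between stage
  centres along planted pseudotime (stage rank scaled to [0, 1] plus
  within-stage jitter), giving the principal curve a continuous
  target. X/Y silencing and escape activation are step functions of
  the assigned stage, so a silencing factor of 0 yields exactly zero
  X counts in that stage.
* **MSCI.** X/Y means are multiplied by per-stage silencing factors
  (defaults 0.8 → 0.6 → 0.1 → 0.1 → 0.5 → 0.5 on X). X genes join
  stage programmes at the same rate as autosomes; if X genes were
  always on while autosomes cycled, the X:A ratio would be biased up
  by the on-rate ratio rather than reflecting the silencing factor.
* **Escape genes.** 20 X genes at a near-zero mean of 0.05 expected
  counts per cell before the activation stage (RS) and
  $0.05 \cdot 2^{6}$ after; they are exempt from the silencing factor —
  that is what escaping means. Their means are planted on the absolute
  scale so the group-mean log2FC equals the planted effect without
  library-size distortion.
* **Ambient and empties.** The ambient profile is the
  library-size-weighted mean of all cell expectation profiles (the
  simplest model consistent with ambient RNA from lysed cells — an
  assumption, recorded in the truth object, not a claim about real
  libraries). Empties are multinomial draws with totals uniform on
  [20, 150].
* **Noise.** Negative binomial with dispersion 0.1 (the overdispersion
  the differential module assumes); per-cell mitochondrial fraction
  Beta(2, 60) (~3%); per-cell library sizes log-normal (sdlog 0.3)
  around the stage mean; two batches with optional per-gene log2
  shifts (0 by default).
* **Bulk.** A bulk sample is a multinomial draw of `depth` reads from
  the composition-weighted stage expectation profiles.
  `first_wave_compositions()` emulates the synchronised first wave:
  stage k appears at its onset day and the most advanced available
  stage dominates with exponentially decaying contributions from
  earlier ones.
* **Chromatin.** Uniform background fragments at 0.05/bp, lengths
  50–500 bp; planted (mark, population, gene-set) enrichments add
  Poisson fragments at (fold − 1) × rate inside promoters; three 30-kb
  X blocks take extra H3K9me3 and are tiled by planted L1/ERVK repeat
  annotations.

**What a green test does and does not establish.** The generator
emulates the statistical structure the methods assume — NB counts,
stage mixtures, multinomial ambient, uniform fragment background. It
does not emulate doublets, spliced/unspliced structure, ambient
contamination *inside* real cells, mapping artefacts, sequence content
or batch effects beyond a per-gene shift. A green suite establishes
that the statistics recover what they are defined to recover under
their own model; it cannot certify behaviour under real-data artefacts
the world does not contain.

**Fixture sizing.** Two acceptance fixtures deviate from the default
world for measurement reasons, chosen a priori as one designs a power
analysis. The X:A fixture plants no marker programmes and uses 300 X
genes with baseline sd 1.0: heavily boosted markers shift the
autosomal reference mean, and with 150 heavy-tailed X genes the
sampling error of the X mean alone exceeds the ±0.1 assertion the
criterion makes about the statistic. The droplet-recovery fixture
draws 5000 barcodes exactly from the ambient profile plus 500 planted
cells (50-gene programme at 5×, total 800), the stated design.

## 3. Parameter defaults

| parameter | default | provenance |
|---|---|---|
| QC min genes | 1000 (500 after recovery) | published |
| mitochondrial cap | 10% (strict >) | published |
| droplet FDR | 1% | published |
| ambient pool T, pseudo-count | 100, 0.1 | tooling constants, exposed |
| HVG count | 1000 | published |
| PCA d / SNN k | 50 / 5 (10, 15) | published |
| curve PCs | 3 (10 for recovered-droplet data) | published, both exposed |
| marker FDR | 0.1 | published |
| staging split | 2000 train / rest test | published |
| rho threshold / null size / corr FDR | 0.3 / 100,000 / 0.1 | published |
| X:A expressed fraction | 0.3 (strict >, OR over groups) | published |
| lfc thresholds | 0.5 (pseudo-bulk), 2 (test), 5 (call) | published |
| bulk expression filter | mean count ≥ 10 | published |
| early/late split | day 20, boundary late | published (ambiguous), exposed |
| window / top-N / tolerance | 1000 bp / 1000 / 1500 bp | published |
| promoter window | −2000/+200 | tooling default, exposed |
| fragment quality / length | 10 / 1000 bp | published |
| proportion FDR | 10% | published |

## 4. Numerical choices

* Monte-Carlo and empirical p-values use $(r+1)/(n+1)$ everywhere.
* Marker statistics are computed in log-p space end to end.
* Welch t with zero pooled variance degenerates to a signed sentinel
  statistic; equal means give p = 1, so identical clusters yield no
  markers exactly.
* The threshold test returns `se`, so the $\tau = 0$ identity with the
  plain Wald test is checkable to 1e-12.
* Loess trends fall back to low-order polynomials (HVG) or the median
  (dispersion) below the gene counts where loess is unstable.
* Ties: top-window selection breaks count ties by genomic order;
  min-rank ties break by smaller combined p; z-scoring drops
  zero-variance genes with a warning rather than dividing by zero.
* Degenerate inputs error loudly: empty ambient pools, constant
  matrices, single samples for Z-scores, non-positive size factors,
  compositions off the simplex by more than 1e-8.

## 5. Known limitations

* Batch handling is per-batch blocking/centering only; the published
  mutual-nearest-neighbour correction is out of scope, and the
  generator's batch model (a per-gene log shift) is correspondingly
  simple.
* The droplet test's power against *subtle* compositional deviations is
  limited at small totals; in the planted world high-count cells enter
  through the knee rule, exactly as in the published tooling.
* The staging classifier's probabilities are ridge-regression
  probabilities, not random-forest vote fractions; the tests constrain
  behaviour (accuracy, argmax, ordering), not the algorithm.
* Fisher's exact test on base-level tables treats bases as independent;
  that is the published construction, and its p-values should be read
  as enrichment scores rather than literal error rates.
* `run_pipeline()` keeps state in memory across steps within one call;
  running a dependent step in a fresh session requires the earlier
  steps in the same call (it errors with "missing prerequisite" rather
  than silently reloading partial state).
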