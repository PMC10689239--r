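---
title: "Detecting fear-memory engrams in single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fear-memory engrams in single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scEngram)
```

## The problem

After cued fear conditioning (CFC), only a sparse subset of neurons in a
given cell type — the memory engram — transiently upregulates
activity-regulated genes. Detecting that subset in single-cell RNA-seq is
awkward for two reasons. First, cell identity and cell activation are
entangled: immediate-early genes (IEGs) are so strongly induced that they
can split one cell type into artifactual "active" and "inactive" clusters.
Second, the activated fraction is small (a few percent in some regions), so
median expression per cluster barely moves; the signal lives in the upper
tail of the per-gene expression distribution.

scEngram implements a pipeline built around those two observations:

1. **Taxonomy first, activity excluded.** Cells are clustered on feature
   genes from which 53 IEGs, 6 sex-linked genes and non-neuronal markers
   have been removed, so clusters reflect identity.
2. **Activity second, percentile-based.** Within the fixed taxonomy, a cell
   is called activated (IEG^high) when any gene of an 8-IEG panel (*Arc*,
   *Bdnf*, *Btg2*, *Fos*, *Fosl2*, *Homer1*, *Npas4*, *Nr4a1*) exceeds its
   q-th percentile computed over **all** neurons pooled across timepoints.

Every stage is validated against a seeded synthetic-data generator with
planted ground truth.

## The clustering model

The pipeline follows the three-pass iterative scheme used for whole-brain
cell-type surveys: (1) QC and neurotransmitter-class assignment, (2)
per-class cluster calling and doublet removal, (3) final feature selection
and visualization.

**QC and normalization.** Neurons require ≥ 3,000 UMI and ≥ 2,500 detected
genes per cell (non-neuronal stream: 2,000 / 1,000); thresholds are
inclusive. Each cell vector is then normalized to length 1 and multiplied
by 20,000. We read "length" as the L1 norm (library-size normalization),
because the downstream statistics — fraction-positive, percentile
thresholds — behave sensibly under sum normalization; the L2 reading is
available via `normalize_cells(norm = "l2")`.

**Class assignment.** Per cell, each marker set's mean normalized
expression votes (*Gad2* → GABA, *Slc17a7* → VGLUT1, *Slc17a6* → VGLUT2, a
25-gene pool → non-neuronal); the cluster takes the modal vote. Votes use
normalized expression; published descriptions of such majority votes leave
the mechanics open, and the modal per-cell argmax is the simplest
consistent reading. A cluster is
a putative doublet when its top two class scores sit at a ratio below 2 —
except the permitted VGLUT1/VGLUT2 combination, which co-occurs in real
neurons. The generator plants cross-class doublets (sums of two cells'
rates) to exercise this rule.

**Feature selection.** Eligible genes are expressed in ≥ 5 cells but
< 50 % of cells. Genes are ranked by the residual of log2(CV) above a
least-squares **quadratic** in log2(mean): the empirical CV–mean relation
is curved at the sparse end, and a straight line systematically promotes
ultra-sparse genes (5–60 expressing cells) whose CV it underestimates —
with a quadratic, planted markers occupy essentially all top ranks at study
scale. The number of genes kept is the bending point of the sorted residual
curve.

**Elbow criteria.** `find_elbow()` implements the chord rule: on the
min-max-normalized curve, the index farthest from the chord joining the
first and last points (ties to the smallest index). For *count selection*
from curves with two-scale structure — the gene count from the residual
curve, the PC count from the explained-variance curve — we apply the chord
rule to the **cumulative** curve, which places the bend where the marginal
value crosses the average increment. The plain rule truncates at the first
cliff (the three class markers' residuals; the two class-level PCs) and
measurably destroys cluster recovery, so the cumulative form is the
package's deliberate choice.

**Embedding.** Barnes–Hut t-SNE on correlation distances of the
(batch-corrected) PCA projection, θ = 0.5, learning rate = n/12,
exaggeration 20 within the pipeline (final visualization: perplexity 100,
exaggeration 5), initialized from the first two PCs scaled to sd 1e-4.
Perplexity defaults to a data-driven heuristic: per cell, the elbow of the
sorted correlation-distance curve to its 500 nearest neighbors gives an
optimal neighbor count; the median over cells, clipped to [5, n/4] (the
floor of 5 wins for tiny n), is the perplexity.

**Batch correction.** The two CFC batches (A: HC–8h–24h; B: HC–2h–recall)
are aligned by mean-centering every principal component within each batch
and restoring the global means. This removes location shifts — the dominant
batch artifact in the generator and a reasonable first-order model for real
data — while leaving within-batch geometry untouched. The contract is only
that a batch-mixing statistic does not decrease; any stronger method can be
substituted upstream of `embed_2d()`.

**Cluster calling.** DBSCAN on the 2D embedding; the default radius is the
elbow of the sorted k-distance curve (k = `min_pts`, default 10). Outliers
are removed from cluster membership; `reassign_outliers_knn()` regroups
them by the modal label of their k nearest non-outliers (ties → the single
nearest neighbor's label). Near-identical clusters (mean-profile Pearson
r > 0.995) are auto-merged, replacing manual inspection-driven merging;
an explicit merge list is also honoured. Cells within a cluster are sorted
by a 1D t-SNE of their expression, initialized from the first principal
coordinate — without that initialization 1D t-SNE folds planted gradients.

**Dendrogram.** log2(x+1) expression → cluster means → PCA → Ward linkage
on correlation distance (`ward.D2`). Ward formally assumes Euclidean
geometry; applying its update to a correlation-distance matrix is a
deliberate choice, kept for comparability with MATLAB-style linkage
pipelines, with this caveat. Leaves are permuted by
exact optimal leaf ordering (Bar-Joseph dynamic program, feasible for
cluster-level trees). Branch-point markers score each gene by the
difference in fraction-positive between the two branches of a junction,
averaging per-cluster fractions so unequal cluster sizes do not dominate.

## Spatial correlation mapping

Cluster mean profiles are correlated (Pearson) with spatial units over a
shared feature set: the intersection of feature selections computed
independently on the single-cell and spatial data, after removing
non-neuronal markers (capture spots are micro-bulk and glial genes are
spatially uninformative). Spot expression is correlated on normalized,
untransformed values; a log option was considered and rejected because the
unit-sum normalization already dampens depth effects and the correlation is
computed over a selected feature set.

For the in-situ voxel atlas, genes must pass a quality filter: coverage
> 30 voxels, energy > 5, and mean energy over all voxels > 0.2 (strict
inequalities). We read "> 5 energy" as the maximum over voxels — coverage
and mean are constrained separately, so the remaining useful constraint is
on the peak. Per-cluster region calls take the region with the highest mean
correlation. Dominant maps label each unit with its argmax cluster (ties to
the lower index); weighted maps blend cluster colors by the positive part
of the correlation, normalized per unit — a convex combination, with
all-nonpositive units left as background.

## Engram statistics

**IEG score.** With per-gene thresholds θ_g at the q = 90 percentile
(linear interpolation, zeros included; computed once over all neurons), the
per-cluster fraction of flagged cells per panel gene and timepoint forms an
8 × 5 matrix F; S[t] = Σ_g F[g,t]; the score is max over CFC timepoints of
S[t] − S[HC]. θ_g = 0 (gene zero in more than q % of cells) falls back to
"any positive expression", otherwise strict >. Clusters under 60 cells, or
with any group under 20 cells, are reported but masked as low-confidence.
The HC baseline pools both batches by default; `hc_mode = "batched"`
contrasts each batch against its own home-cage cells and takes the maximum.

**Observed vs expected.** At q = 99, the expected activated fraction of a
cluster at timepoint t is the global flagged fraction at t (a
cluster-size-weighted null, chosen for its simplicity and lack of free
parameters), and the ratio observed/expected quantifies enrichment.

**Fold-change dynamics.** Per gene and timepoint, the mean expression among
threshold-exceeding cells relative to HC, with a pseudocount of 0.1 on both
sides; undefined when no cell qualifies. This conditional-mean definition
is the package's own.

**In-silico trapping DE.** At q = 95, CFC-sampled cells of a cluster split
into IEG^high and IEG^low; d = difference of mean log2(x+1) normalized
expression. We use log expression because the companion display is a
difference-versus-average (MA-style) plot. Top lists keep genes with mean
raw UMI > 1 and at most 100 genes per direction; genes are then ranked
across clusters by how often d > 0.5 within a class.

**Module correlation score.** For each eligible (cluster, timepoint) group
(genes expressed in > 200 class cells; clusters with ≥ 20 cells at every
timepoint), the pairwise Pearson matrix of a module's genes is aggregated
by the mean Fisher z of the off-diagonal entries → a single r̄ → a
two-sided p from the t transform t = r̄ √((n−2)/(1−r̄²)) at the group's
cell count → score = −log10 p, capped at 320 (the double-precision floor).
The matrix→p aggregation is the package's choice: the Fisher-z mean is
smooth and sample-size aware, but note it is conservative: r̄ = 0.3 at
n = 50 gives a score of only ≈ 1.5. The cluster score contrasts the
maximum over CFC groups against the maximum over the batch-specific HC
groups and may be negative. p-values are computed in log space so extreme
correlations do not underflow; at r = 0 the p is exactly 1.

**Single-gene screens.** For a target gene (e.g. *Bdnf*, *Nlgn1*), genes
expressed in > 5 cells of a group are correlated with the target; genes
with p < 0.01 count as correlated, and the ranking is the number of
(cluster, CFC timepoint) groups in which a gene is significant. The top 200
are emitted for downstream enrichment tools.

## Photometry

The isosbestic control channel (405 nm) is fitted onto the signal channel
(465 nm) by least squares; ΔF/F = (signal − fit)/fit removes bleaching and
movement artifacts shared by the channels (a residual-only mode is
available). Responses are aligned to events, averaged into 0.5-s bins over
a −5…+5 s window, and z-scored per event against the 10 pre-event baseline
bins — which therefore have mean 0 and sd 1 exactly. Bins are aligned to
event time, not the acquisition clock; events without a full window are
dropped, and zero-variance baselines mark the event invalid.

## The synthetic-data generator

`generate_counts()` draws UMI counts from a negative binomial
(gamma–Poisson) law with shared dispersion φ (variance μ + φμ²,
default φ = 0.3):

* **Baseline abundances** are log-normal with sdlog 2, matching the heavy
  skew of real UMI data in which most genes are detected in well under half
  of the cells — the feature-selection gates assume this.
* **Types and classes**: each type gets `markers_per_type` marker genes at
  `marker_fold` (default 8×) over a fixed baseline (off-type mean 0.5), and
  each class its canonical marker (*Gad2*/*Slc17a7*/*Slc17a6*) at 20×
  within class and 0 outside.
* **Design**: five timepoints (HC, 2h, 8h, 24h, recall) in two batches
  (A: HC–8h–24h; B: HC–2h–recall; HC split across both), log-normal library
  sizes (mean 6,000 UMI, sdlog 0.3), per-batch per-gene log-normal effects
  (sd 0.15), and cross-class doublets (2 %) labeled in truth.
* **Engrams**: per planted type, cells at the stated timepoints activate
  with the stated probability; activated cells have the IEG panel scaled by
  `panel_fold` and optional signature genes by 2^log2FC. Signature genes
  get an expressed baseline, since the trapping-DE rule only evaluates
  genes with mean UMI > 1.
* **Modules**: module genes share one multiplicative log-normal latent
  factor per cell in active (type, timepoint) groups; the default loading
  0.42 at module base mean 10 targets pairwise r ≈ 0.3 via
  r = (v−1)/(1/λ + φv + v − 1), v = e^{σ²}.
* **Spatial targets**: spots are Poisson micro-bulk mixtures dominated
  (weight 0.85) by their region's types, at a depth of 1.5 UMI per gene —
  the per-gene capture depth of real spot data, keeping most genes sparse
  across spots; voxel atlases elevate each type's markers in its region and
  plant one gene violating each quality rule (30-voxel coverage, max
  energy ≤ 5, mean ≤ 0.2, all-zero).
* **Photometry**: both channels share an exponential bleaching trend and a
  smooth motion artifact; only the signal channel carries a 5-s plateau
  transient whose amplitude is calibrated so the expected post-event z
  equals the requested amplitude.

What the generator does **not** emulate: empirical amygdala expression
distributions or gene names (markers are synthetic symbols), ambient RNA,
per-cell (as opposed to cluster-level) doublet structure, spatial
within-region gradients, or hemodynamic artifacts in photometry. Passing
tests therefore demonstrate that the statistics recover the structure they
are designed for under a faithful noise model — not that any particular
biological dataset will behave as cleanly.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation (R type 7), zeros included.
* Division guards: doublet rule never flags when the second score is 0;
  observed/expected is undefined when the expectation is 0; zero-variance
  spatial units are NA, not 0; zero-variance screen targets skip the group.
* `correlation_p` is evaluated in log space; |r| = 1 is capped at the
  smallest representable double rather than returning 0.
* Constant series give elbow index 1; DBSCAN with all points outliers is an
  error that suggests parameter changes; clusters of < 3 cells keep their
  input order; dendrograms accept singleton clusters (mean = the cell).
* Every stochastic step takes an explicit seed (default 0) and restores the
  caller's RNG state.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at 12 types × 300 cells × 2,000
genes (cluster recovery, ARI ≥ 0.9), 20 seeded engram runs at 12 types ×
200 cells × 300 genes, 200 null simulations at 500 cells × 60 genes, 20
module-recovery seeds at 2 types × 250 cells, and spot/voxel targets with
300 spots / 384 voxels — sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping every Monte-Carlo criterion
well-determined.

## Known limitations

* The location-shift batch correction does not address batch-specific
  expression *scaling*; a stronger aligner can be plugged in between
  `pca_project()` and `embed_2d()`.
* The Fisher-z module aggregation is conservative at small n (see above);
  rankings between clusters are reliable, absolute score magnitudes should
  not be compared across different group sizes.
* Ward-on-correlation is a heuristic; dendrogram topology near short
  internal branches should not be over-interpreted.
* The IEG score's null spread grows with library-size dispersion, because
  thresholding normalized expression couples panel genes within a cell;
  scores within ±0.3 of zero should be treated as noise at 100-cell groups.
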