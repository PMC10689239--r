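# scEngram

Tools for finding fear-memory **engram cells** — the sparse subsets of
neurons that transcriptionally respond to fear learning — in single-cell
RNA-seq of the mouse amygdala, together with the cell-type taxonomy and
spatial-mapping machinery the engram statistics depend on.

The package is aimed at analysts working with UMI count matrices from
cued-fear-conditioning (CFC) designs: home-cage controls (HC) plus animals
sampled 2 h, 8 h and 24 h after conditioning and 2 h after recall,
collected in two batches (A: HC–8h–24h; B: HC–2h–recall).

## What it computes

**Taxonomy.** Iterative clustering with identity/activity separation: QC
(≥ 3,000 UMI and ≥ 2,500 genes per neuron), L1 normalization to 20,000,
neurotransmitter-class assignment by marker vote (*Gad2* → GABA,
*Slc17a7* → VGLUT1, *Slc17a6* → VGLUT2), doublet-cluster exclusion by the
score-ratio-< 2 rule, CV–mean feature selection with a 53-IEG + sex-gene
exclusion list, PCA with elbow-chosen dimensionality, batch correction,
correlation-distance t-SNE (θ = 0.5, learning rate n/12, exaggeration 20),
DBSCAN cluster calling with kNN outlier regrouping, Ward/correlation
dendrograms with optimal leaf ordering, and branch-point markers ranked by
the difference in fraction-positive between branches.

**Spatial mapping.** Pearson correlation of cluster mean profiles with
spatial-transcriptomics capture spots and with in-situ-hybridization voxel
atlases (gene quality filter: coverage > 30 voxels, energy > 5, mean
> 0.2), region-wise summaries, and dominant / weighted colormaps.

**Engram statistics.** With per-gene thresholds θ_g at the 90th percentile
of the 8-IEG panel (*Arc*, *Bdnf*, *Btg2*, *Fos*, *Fosl2*, *Homer1*,
*Npas4*, *Nr4a1*) over all neurons, a cell is IEG^high if any panel gene
exceeds its θ_g. Per cluster, F[g,t] is the flagged fraction per gene and
timepoint, S[t] = Σ_g F[g,t], and the **IEG score** is

    score = max over t ∈ {2h, 8h, 24h, recall} of ( S[t] − S[HC] ).

Also: observed-vs-expected activation enrichment (q = 99), time-resolved
conditional fold changes, in-silico trapping differential expression
(IEG^high vs IEG^low at q = 95; d = Δ mean log2(x+1); top-100 with mean
UMI > 1; d > 0.5 cluster-frequency ranking), gene-module **correlation
scores** (mean Fisher-z of the pairwise Pearson matrix → r̄ → two-sided t
p-value → −log10 p; cluster score = max(CFC) − max(HC batch)),
transcriptome-wide single-gene correlation screens, and event-aligned
fiber-photometry z-scoring after isosbestic detrending.

**Synthetic data.** A seeded generator plants known cell types, engram
subsets, coregulated modules, batch effects, doublets, spatial regions,
voxel atlases and photometry transients, so every statistic is tested
against ground truth. See the vignette (`vignettes/engram-analysis.Rmd`)
for the model and its assumptions.

## Worked example

Simulate a CFC dataset in which cell type `GABA_1` contains a planted
engram (30 % of its cells activate at 2 h and 24 h, panel genes scaled
5-fold), then score every type:

```r
library(scEngram)

design <- synth_design(
  n_types_per_class = c(GABA = 2, VGLUT1 = 2, VGLUT2 = 2, NonNeuronal = 0),
  cells_per_type_per_timepoint = 50, n_genes = 500,
  engram_spec = list(list(type = "GABA_1", prob = c("2h" = 0.3, "24h" = 0.3),
                          panel_fold = 5)),
  seed = 1)
sim <- generate_counts(design)
m <- normalize_cells(sim$matrix)
#> count_matrix: 500 genes x 1530 cells (normalized)
#>   timepoints: HC=308 2h=305 8h=304 24h=306 recall=307

thr    <- activation_thresholds(m, q = 90)
flags  <- flag_active(m, thr)
tables <- activation_tables(flags, sim$truth$type, m$cell_meta$timepoint)
tables
#> activation_tables: 25 clusters, timepoints HC 2h 8h 24h recall
#>              cluster score n_cells min_group low_confidence
#> 1             GABA_1  1.90     250        50          FALSE
#> 18   VGLUT2_1+GABA_2  1.00       2         0           TRUE
#> 21          VGLUT2_2  0.56     250        50          FALSE
#> 5             GABA_2  0.36     250        50          FALSE
#> 8           VGLUT1_1  0.00     250        50          FALSE
#> ...

round(tables$S$GABA_1, 2)
#>     HC     2h     8h    24h recall
#>   0.64   2.54   0.60   2.20   0.80
```

The planted engram type tops the ranking: its summed activated fraction S
rises from 0.64 in home-cage to 2.54 at 2 h and 2.20 at 24 h — exactly the
planted timepoints — giving an IEG score of 1.90, while types without a
planted engram score near 0. The only other entries with elevated scores
are tiny doublet pseudo-clusters, which the confidence mask
(`low_confidence`; clusters < 60 cells or any group < 20 cells) flags for
exclusion.

`run_pipeline(demo_config())` chains the full analysis (simulate → QC →
cluster → engram → correlation) on synthetic data and writes cluster
tables, IEG scores and correlation scores as TSV plus a reproducible run
manifest.

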