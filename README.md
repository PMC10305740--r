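# agenoise

Aging tissues do not just shift their mean transcriptional programs — cells
of the same type also drift apart from one another. `agenoise` implements the
analysis stack for quantifying this **age-related transcriptional noise** in
single-nucleus RNA-seq (snRNA-seq), together with the per-cell-type
differential-expression, gene-set-scoring and regulon-ranking stages that
typically surround it in an aging study of a multi-sample design (e.g. eight
young and eight old animals). It is aimed at computational biologists who
have a UMI count matrix with per-nucleus sample, age-group and cell-type
labels and want these analyses as plain, tested R functions that take and
return tibbles.

## The statistics

**Transcriptional noise.** For each cell type with at least 10 young and 10
old cells, the procedure (i) equalises library sizes by exact without-
replacement UMI down-sampling (multivariate hypergeometric) to a common
target, (ii) balances cell numbers by sampling the larger age group down to
the smaller, (iii) computes each cell's noise as the Euclidean distance
between its expression vector *x<sub>c</sub>* (log1p of down-sampled counts)
and its cell-type/age-group centroid:

> d<sub>c</sub> = ‖ x<sub>c</sub> − mean( x : same cell type & age group ) ‖₂

and (iv) summarises each cell type as a log2 old/young ratio by two
estimators: the **single-cell** estimator log2( mean d over old cells /
mean d over young cells ) and the **sample-average** estimator, which first
averages distances within each animal so every animal gets equal weight.

**Differential expression.** Per cell type, old vs young, two-sided Wilcoxon
rank-sum per gene on the log-normalised layer (exact null distribution for
small groups, tie-corrected normal approximation otherwise), fold change as
ln of the ratio of group means of expm1(normalised), Benjamini–Hochberg
adjustment within the cell type, and significance at |LogFC| > 0.25 and
adjusted P < 0.05. One-vs-rest Welch t-tests (|LogFC| > 0.5) provide marker
genes. Genes significant in at least five cell types are reported as shared
DEGs with consistently-up / consistently-down / mixed direction classes.

**Gene-set scores.** Per-cell module scores against expression-bin-matched
control genes (24 bins, 100 controls per set gene), compared between age
groups per cell type by rank-sum test with kernel-density peak locations.

**Regulon hubs.** Given a TF→target map, the package counts differentially
expressed targets per TF per cell type, computes hypergeometric enrichment
against the tested-gene universe, and flags hub TFs whose own transcript is
down-regulated in more than five cell types.

Everything is exercisable without external data through a negative-binomial
simulator (`simulation_config()` / `simulate_dataset()`) with known ground
truth: per-gene lognormal baselines, cell-type programs, per-sample and
per-cell lognormal factors, configurable old-cell fold changes and
dispersion inflation, and a mitochondrial gene fraction for the QC filters
(nuclei with fewer than 200 detected genes or more than 1% mitochondrial
UMIs are discarded).

## Worked example

Simulate a desk-scale study (4 + 4 animals, 150 nuclei each, 1,000 genes,
3 cell types) in which old FastIIA nuclei get 3× dispersion inflation and 40
genes halved, then run the pipeline stages:

```r
library(agenoise)

cfg <- simulation_config(
  age_dispersion = data.frame(cell_type = "FastIIA", multiplier = 3),
  age_de = data.frame(cell_type = "FastIIA", gene = 1:40, fold_change = 0.5),
  seed = 1)
sim <- simulate_dataset(cfg)

ds <- sim$dataset |> filter_cells() |> normalize_counts()
#> filter_cells: 1200 cells in; 22 below 200 genes, 4 above mito 0.01; 1174 retained

tidy(transcriptional_noise(ds, seed = 1))
#> # A tibble: 3 × 5
#>   cell_type log2_ratio_single_cell log2_ratio_sample_average n_cells_young
#> 1 FastIIA                  0.0929                    0.0924             256
#> 2 FastIIX                  0.00360                   0.00370            194
#> 3 SlowI                    0.00232                   0.00274            118
```

Only the noise-inflated cell type moves away from zero, under both
estimators. The same holds for the planted expression changes:

```r
degs <- run_deg(ds)
glance(degs)
#> # A tibble: 3 × 5
#>   cell_type n_genes n_deg  n_up n_down
#> 1 FastIIA      1000    40     0     40
#> 2 FastIIX      1000     0     0      0
#> 3 SlowI        1000     0     0      0

sc <- module_score(ds, sim$truth$true_de$gene, name = "planted_set", seed = 1)
compare_group_scores(sc, ds$cells)
#>   set         cell_type median_young median_old  p_value
#> 1 planted_set FastIIA         0.0845    -0.312   2.65e-68
#> 2 planted_set FastIIX         0.0383     0.0394  9.15e- 1
#> 3 planted_set SlowI           0.152      0.124   5.76e- 1
```

All 40 planted genes are recovered as down-regulated DEGs in FastIIA with no
false calls elsewhere, and the planted set's module score drops only in old
FastIIA nuclei. `autoplot()` on a noise result draws the two-estimator
scatter; `plot_deg_counts()` and `plot_score_density()` cover the other
result types. `run_pipeline(config, out_dir)` chains every stage
(simulation or 10x-style input → QC → noise → DEG → shared DEGs → scores →
hub TFs) and writes deterministic, headered TSVs.

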