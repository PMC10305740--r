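---
title: "Quantifying age-related transcriptional noise in snRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying age-related transcriptional noise in snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agenoise)
```

## The problem

Aging shifts mean expression programs, but it also loosens the regulation
that keeps cells of one type transcriptionally similar. In multi-sample
single-nucleus RNA-seq of a tissue such as skeletal muscle — several young
and several old animals, each contributing thousands of nuclei labelled
with a cell type — we want to ask, per cell type: did cell-to-cell
variability increase with age, which genes changed, did curated gene sets
(for instance a transcription factor's target regulon) lose activity, and
which regulators look like hubs of the change?

Two nuisances make the variability question subtle. Cells differ in
sequencing depth, and deeper cells look less noisy simply because counting
noise shrinks relative to signal; and cell types differ in abundance
between groups, so group mean vectors are estimated with different
precision. The noise procedure removes both before measuring anything.

## The noise statistic

For each cell type with at least `min_cells_per_group` (default 10) young
and old cells:

1. **Library-size equalisation.** Every cell's UMIs are down-sampled
   *without replacement* to a common target (default: the minimum library
   size among cells entering the analysis). Sampling a cell's UMI multiset
   without replacement is a multivariate hypergeometric draw; each cell's
   new total equals the target exactly and no per-gene count can increase.
   We chose exact subsampling over binomial thinning because the UMIs are a
   finite population and exact total conservation is a testable contract.
2. **Cell-number balancing.** Within the cell type, the larger age group is
   sampled without replacement down to the size of the smaller, so both
   centroids are estimated from the same number of cells.
3. **Distance to centroid.** On `log1p` of the down-sampled counts (the
   default `distance_layer`; raw counts are available), each cell's noise is
   its Euclidean distance to the mean expression vector of its own
   (cell type, age group) cells.
4. **Ratios.** Per cell type, the single-cell estimator is
   `log2(mean(d_old) / mean(d_young))`; the sample-average estimator first
   averages distances within each animal and ratios the animal-level means,
   so one animal with many cells cannot dominate. We use the ratio of means
   rather than a mean of per-cell ratios because per-cell ratios are
   undefined — noise is a group-relative quantity.

Down-sampling and balancing are random, so the whole pass is driven by an
explicit seed and can be repeated (`n_resamples`) with the estimators
averaged; one pass is the default. Two decisions here were genuinely open:
whether library equalisation happens before or after cell balancing
(`equalize_first = TRUE` by default — the target then reflects all cells of
analysed types, and balancing operates on already-comparable cells; the
other order is available), and which expression space distances live in
(log-scale by default, since Euclidean distance on raw counts is dominated
by the few highest-expressed genes). An alternative noise summary based on
per-gene coefficients of variation is sometimes quoted in this literature;
this package implements only the centroid-distance procedure, which is the
one defined operationally, and does not provide a CV variant.

```{r noise-demo}
cfg <- simulation_config(
  age_dispersion = data.frame(cell_type = "FastIIA", multiplier = 3),
  seed = 1)
sim <- simulate_dataset(cfg)
ds <- sim$dataset |> filter_cells(verbose = FALSE) |> normalize_counts()
noise <- transcriptional_noise(ds, seed = 1)
tidy(noise)
```

## Quality control and normalisation

Nuclei with fewer than 200 detected genes or a mitochondrial UMI fraction
above 1% are discarded (`qc_thresholds()`), with strict inequalities so
boundary cells survive; mitochondrial genes are recognised by the `MT-`
name prefix or an explicit flag column. Cluster-level QC (dropping whole
clusters that lack markers) requires the upstream clustering and is out of
scope — cell-type labels are inputs here.

The normalized layer is log counts-per-10k: `log1p(count * 1e4 / total)`.
A variance-stabilising regression transform would also work, but every
downstream statistic in this package — rank-sum tests, centroid distances,
bin-matched module scores — needs only a monotone, library-size-corrected
layer, and the simple transform keeps the pipeline self-contained and easy
to reason about in tests.

## Differential expression

`wilcoxon_deg()` tests each gene old vs young within a cell type with a
two-sided Wilcoxon rank-sum test. Numerically: when both groups have at
most 25 cells and the gene has no tied values, the p-value is the exact
doubled tail of the null rank-sum distribution; otherwise a normal
approximation with tie correction and continuity correction is used. A
constant gene returns p = 1 and log-FC 0. The fold change is
`log((mean(expm1(old)) + 1e-9) / (mean(expm1(young)) + 1e-9))` in natural-log
units — the convention of the single-cell tools under which the standard
0.25 cutoff is interpreted; the pseudocount and log base are configurable.
BH adjustment is applied within each cell type (not globally) because DEG
counts are reported per cell type. No minimum-detection-fraction filter is
applied by default (`min_detect_frac = 0`), since the reference workflow
does not state one; it is available for sparser data.

Shared-DEG aggregation (`shared_degs()`, default: significant in at least
five cell types) classifies genes as consistently up, consistently down, or
mixed — the mixed class exists because the contract must cover it even
though direction-consistent sharing is the common outcome. `ttest_markers()`
provides one-vs-rest Welch t-test markers at |LogFC| > 0.5.

## Gene-set scores and regulon hubs

`module_score()` ranks genes by mean normalized expression over all cells
(globally, not per cell type — cells are scored once and then split by type
for comparison), cuts them into `n_bins = 24` equal-size bins, draws
`n_ctrl = 100` control genes per set gene from its bin (with replacement
only when a bin is smaller than the draw), and scores each cell as mean set
expression minus mean pooled-control expression. The defaults follow the
widely used module-scoring convention; both are configurable. Group
comparisons use the same rank-sum machinery, plus the mode of a Gaussian
kernel density estimate (Silverman's rule-of-thumb bandwidth, `bw.nrd0`) as
a reproducible "peak position" for plots.

`regulon_deg_counts()`, `target_enrichment()` and `rank_hub_tfs()` treat
the TF→target map as an input (regulon inference belongs to dedicated GRN
tools). Enrichment is a one-sided hypergeometric tail over the universe of
genes *tested* in that cell type — using all annotated genes would reward
detection bias. A hub requires the TF's own transcript to be
down-significant in **more than** `min_self_down_celltypes = 5` cell types
(strict, i.e. at least 6); ranking is by self-down breadth, then total DE
target count, then name, so ties are deterministic.

## The simulator: what it emulates and what it does not

`simulate_dataset()` draws negative-binomial counts with mean
`baseline × cell-type program × sample factor × library factor × age fold
change` and dispersion θ (variance μ + μ²/θ), with θ *divided* by an age
multiplier for old cells of noise-affected types — variance inflation with
the mean untouched, which is exactly what the noise statistic should
detect and what differential expression should ignore. Defaults are desk
scale: 4 + 4 samples, 150 nuclei per sample, 1,000 genes, 3 cell types,
lognormal(−1, 1) baselines, θ = 2, 30% library-size spread, 15% sample
effects, 1.5% mitochondrial genes at a quarter of the usual baseline
(nuclear preparations carry little mitochondrial RNA). Sample effects are
gene-independent by design so that a null configuration is exchangeable
across age relabelings — the property the calibration tests rely on.

`hub_simulation_config()` plants a positive control for regulon analysis:
one well-expressed gene (the hub TF transcript, pinned baseline mean 4) and
20 targets down-regulated to 0.25× in old cells of six cell types. The
pinned mean matters: a planted effect on a weakly expressed gene is
statistically marginal in small cell types and would make ground-truth
recovery a coin flip rather than a test of the machinery.
`simulate_regulons()` then wires a TF→target map whose designated hub and
half of its targets are those true down-regulated genes.

The simulator does **not** model ambient RNA, doublets, batch chemistry,
UMI collisions, per-gene sample interactions, or realistic gene–gene
correlation. Passing tests therefore demonstrate that the statistics do
what they claim under a clean generative model — calibrated nulls, recovery
of planted effects — not that any particular biological dataset will behave
as cleanly.

## Determinism and test scale

Every random step takes an explicit seed; `run_pipeline()` derives
per-stage seeds from a single config seed by a fixed offset rule, and
identical configs produce byte-identical TSV outputs. The test suite runs
the calibration studies at the desk scale above: 10 replicate null
simulations and 10 dispersion-inflated simulations for the noise
calibration/sensitivity checks, five pooled simulations of 1,000 genes ×
600 cells for DEG sensitivity (observed ≈ 0.85) and FDR (observed ≈ 0.08
at the |LogFC| > 0.25, adjusted P < 0.05 cutoffs — slightly above the BH
level because animal-level random effects induce weak within-group
correlation, the familiar pseudoreplication caveat of cell-level tests),
20 hub-recovery replicates, and 10,000 null genes for the type-I-rate
check (observed ≈ 0.048; sparse counts make the rank-sum mildly
conservative). These sizes were chosen so the whole suite runs in a few
minutes on one core while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

- Cell-level DE tests treat cells as independent; with few animals per
  group, animal-level confounding inflates the effective false-discovery
  rate somewhat (see above). A pseudobulk or mixed-model layer is a
  deliberate non-goal here.
- The noise statistic is a single summary per cell type; it does not
  decompose noise per gene.
- Regulon maps are taken at face value; no motif or binding evidence is
  re-examined.
- The command-line surface is the R API plus `run_pipeline()`; no shell
  executable is shipped, as the package is meant to be driven from R
  scripts and notebooks.
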