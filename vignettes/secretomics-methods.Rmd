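---
title: "Models and methods behind secretomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind secretomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomics)
```

# Scope

`secretomics` analyzes single-cell cytokine secretion profiles of the kind
produced by antibody-barcoded 32-plex single-cell ELISA assays: each T cell
contributes a vector of 32 mean fluorescence intensities (MFI), annotated
with its sample, patient, tissue compartment (peripheral blood, PB, or bone
marrow, BM), therapy timepoint (baseline or two months after checkpoint
blockade, post-IO), T-cell subset (CD4/CD8) and, at the sample level, the
patient's therapy response (complete responder, CR, vs nonresponder, NR)
and age. The package covers four analysis layers plus a simulator:

1. **Polyfunctional strength** — secretion calling, polyfunctionality, the
   polyfunctional strength index (PSI), and pseudobulk contrasts.
2. **Embedding** — outlier filtering, log normalization, PCA, patient-level
   batch correction, kNN graph, Leiden clustering, UMAP.
3. **Neighborhood differential abundance** — Milo-style overlapping kNN
   neighborhoods tested for timepoint shifts with a spatially weighted FDR,
   and timepoint-exclusivity classification.
4. **De novo polyfunctional groups** — hierarchical clustering of
   cluster-level cytokine signatures and responder-vs-nonresponder tests of
   group proportions.

# The polyfunctional strength index

A cytokine is *secreted* by a cell iff its MFI strictly exceeds that
cytokine's threshold; the default threshold is 0, so any nonzero
(background-subtracted) signal counts, and per-cytokine gates can be
supplied for instruments that retain background. A cell is *polyfunctional*
iff it secretes **two or more** of the 32 panel cytokines — decided on the
full panel, never within a group. For a sample-by-subset block and a
functional group $g$,

$$\mathrm{PSI}_g \;=\; \underbrace{100\cdot\frac{n_{\mathrm{poly}}}{n}}_{\text{polyfunctional \%}}
\;\times\; \underbrace{\sum_{\text{poly cells}}\ \sum_{c \,\in\, g,\ \text{secreted}} \mathrm{MFI}_c}_{\text{group-restricted MFI sum}}.$$

Design choices worth stating plainly:

* **Percentage scale.** The polyfunctional fraction enters on the 0–100
  scale, not 0–1. Only relative comparisons matter downstream, but the
  scale is documented so PSI values are comparable across tools.
* **Group restriction.** Only the MFI sum is group-restricted;
  polyfunctionality is panel-wide. Consequently the five group MFI sums add
  up exactly to the overall MFI sum (a tested invariant). A per-group
  polyfunctionality variant exists behind `group_polyfunctionality = TRUE`.
* **Sum vs mean.** The MFI term is a sum over polyfunctional cells; an
  averaging variant (`mfi_stat = "mean"`) exists for sensitivity analysis.
* **Empty blocks.** A block with zero cells reports `NA`, not 0 — a zero
  PSI means "no polyfunctional signal", which is information.

Pseudobulk contrasts use a paired two-sided t test for within-patient
comparisons (PB vs BM at one timepoint; baseline vs post-IO within a
tissue) and a two-sided Wilcoxon rank-sum test for the independent CR vs NR
comparison; a paired Wilcoxon signed-rank variant is available via
`test = "wilcoxon"` on the paired contrasts. ("Paired rank-sum" is a
contradiction in terms — rank-sum is the unpaired test — so both variants
are exposed and the choice is explicit.) All-zero paired differences are
reported as degenerate with p = 1 rather than NaN; strata with too few
pairs are flagged untestable rather than dropped. p values are
Benjamini–Hochberg adjusted within each contrast family, and both raw
p < 0.05 and q < 0.05 calls are reported, since small cohorts are often
read at the raw level. Age associations use Spearman correlation per
tissue-by-subset stratum.

# The embedding pipeline

* **Outlier filter.** A cell is removed iff any single cytokine exceeds
  3,000 MFI (strict inequality). The per-channel reading of "over 3,000
  MFI" targets extreme single measurements; a total-MFI dialect
  (`outlier_mode = "total"`) is available. The filter is idempotent and
  reports per-sample removal counts.
* **Normalization.** The standard global-scaling log transform,
  $x \mapsto \ln(1 + 10^4\, x/\mathrm{total})$, per cell. Zero-total cells
  map to zero rows and are flagged.
* **Variable features.** Cytokines are ranked by variance standardized
  against a loess mean–variance trend. With only 32 channels the default
  keeps all of them; the ranking exists for larger panels.
* **PCA.** Feature-centered, unscaled; 10 components by default (no value
  is canonical for 32-plex data; 10 retains essentially all structure in
  practice). Component signs are fixed by making the largest-magnitude
  loading positive, so results are bit-reproducible.
* **Batch correction.** Patient-level offsets are removed by an iterative
  soft-clustering correction: diversity-penalized soft k-means in PC
  space, then per-cluster removal of batch-specific centroid offsets. The
  assignment bandwidth anneals from the global data scale down to the
  within-cluster scale, so early iterations can bridge (and remove) large
  uniform shifts while later ones refine local offsets. The algorithm is
  defined by contract, not as a port of any reference implementation: on
  pure batch shifts it must raise (never lower) a kNN batch-mixing
  entropy, and on composition-confounded biology (the same populations at
  different proportions per batch, no shift) it must not split or merge
  populations — there, mixed clusters estimate near-zero offsets and the
  data pass through essentially unchanged. Because uniform multiplicative
  batch effects cancel in the library-size normalization, well-mixed data
  can be left with nothing to correct; in that regime per-batch
  translations estimated from composition noise would *de-mix*
  neighborhoods. The implementation therefore accepts its output only
  when the mixing entropy does not decrease, and otherwise returns the
  input unchanged (`accepted` attribute). One case is unidentifiable in
  principle: a population present in only one batch looks locally
  identical to a shifted copy of another batch's population, and any
  method that can remove large pure shifts will tend to merge such
  batch-exclusive populations; with patients as batches this design does
  not arise (every patient contributes the same T-cell biology). An
  escape hatch accepts externally corrected PCs.
* **kNN graph and clustering.** Exact Euclidean kNN (k = 20 by default),
  symmetrized; Leiden community detection on modularity at resolution 0.8.
  Labels are size-ordered and 0-based. Modularity clustering of a kNN graph
  *over-partitions* large homogeneous populations by design — on three
  perfectly separated simulated populations it returns ~10 communities at
  resolution 0.8, each a pure fragment. This is the expected regime (the
  reference workflow reports 8 CD4 / 7 CD8 clusters from what are likely
  fewer macro-phenotypes) and is exactly what the de novo group-derivation
  stage merges again. To recover broad populations directly, use a low
  resolution (~0.1); `sweep_resolution()` tabulates community counts over
  a grid.
* **UMAP.** Two-dimensional, seed-deterministic, visualization only — no
  downstream statistic consumes UMAP coordinates (clustering operates on
  corrected PCs; this is asserted by the interface, which never passes
  `umap` into the statistical stages).

# Neighborhood differential abundance

Index cells are drawn uniformly (10% by default), refined to the member of
their kNN closest to the neighborhood mean in PC space, deduplicated; a
neighborhood is an index cell plus its k nearest neighbors, so
neighborhoods partially overlap. Member cells are counted per sample, and
each neighborhood is tested with a negative-binomial log-linear model

$$y_{ns} \sim \mathrm{NB}(\mu_{ns}, \phi_n),\qquad
\log \mu_{ns} = \beta_{0n} + \beta_{1n}\,[\text{post-IO}]_s + \log T_s,$$

where $T_s$ is the total cells of sample $s$. The dispersion $\phi_n$ is
estimated by method of moments from a Poisson fit's Pearson residuals and
shrunk halfway toward the cross-neighborhood median — individual
neighborhoods have too few samples to estimate dispersion stably, and the
shared component borrows strength exactly where Milo borrows it from
edgeR. $\beta_1$ (the natural-log fold-change, post-IO vs baseline) is
tested with a two-sided Wald z test. The normal reference was chosen over
a t reference empirically: under permutation of sample labels the Wald
statistic has unit variance and the z test holds its nominal size (type-I
error ≈ 0.05), while a t(n−2) reference is conservative (≈ 0.026).
All-zero neighborhoods, or neighborhoods with cells in only one arm and
fewer than 3 cells, are flagged untestable rather than tested.

Multiplicity is handled with the spatially weighted Benjamini–Hochberg
procedure: weights proportional to the reciprocal of each neighborhood's
kth-NN distance, so densely tiled regions (whose neighborhoods overlap
heavily) are not over-penalized. With equal distances it reduces *exactly*
to plain BH (a tested identity); zero distances are capped at the smallest
positive distance.

Exclusivity is test-free: a neighborhood is baseline-only / post-only /
mixed purely by its members' timepoints. The summary reports counts and
percentages over **all** neighborhoods (this is the reading that makes
982 of 2,158 come out at 45.5%), with the FDR < 0.1-restricted counts as a
separate column. Percentages print to one decimal, except values below 1%,
which keep two (0.85%, not 0.8%).

**Choosing k.** The pipeline default (k = 20) matches the clustering
stage. For DA power the neighborhood must be able to see every sample:
we size k so that mean neighborhood size is at least ~5× the number of
samples (the Milo sizing rule); the cohort-scale checks in this package
use k = 100 with 12 samples of 1,000 cells.

# De novo polyfunctional groups

Cluster-level signatures are per-cluster means of the normalized matrix,
z-scored per cytokine across clusters. Raw z-scoring has a trap: *any* set
of k cluster means has SD-1 z-scores, so a cytokine whose means differ only
by sampling noise looks as "signature-like" as a real marker. The SD is
therefore floored at the mean per-cytokine SD, which leaves genuine
markers (SD at or above the mean) untouched and shrinks noise channels
toward zero. Ward-linkage dendrograms (Euclidean distance on the z matrix)
order rows and columns; the cluster dendrogram cut into `k_groups`
branches defines the groups (defaults 5 for CD4, 6 for CD8, matching the
reference analysis; always configurable). A group's signature cytokines
are those whose *cell-weighted* group-mean z exceeds +0.5 — cell-weighting
prevents a tiny member cluster from dominating the group block, and +0.5
is an explicit, configurable convention for "drawn box on the heatmap".
Group proportions per sample are tested CR vs NR per tissue at baseline
with the Wilcoxon rank-sum test (raw p reported alongside BH q).

# The cohort simulator

`simulate_cohort()` draws each cell's subpopulation from condition-specific
mixing weights (tissue × timepoint × response), then each cytokine is
secreted with the population's probability and a secreted MFI is drawn
log-normally:

$$\mathrm{MFI}_{ic} \;=\; Z_{ic}\,\exp\!\big(\mu_{p(i),c} + b_{\mathrm{pat}(i)}
 + s\,( \mathrm{age} - 65)\,[c = c_{\mathrm{age}}] + \sigma_c \varepsilon_{ic}\big),
 \qquad Z_{ic}\sim\mathrm{Bern}(\pi_{p(i),c}).$$

What it emulates, and the defaults that define the simulated study
conditions:

* **Zero-inflated log-normal secretion.** Signature channels secrete with
  probability 0.9 at median ~300 a.u. (log-SD 0.4); incidental secretion
  with probability 0.05 at median ~60 a.u. Non-secretion is an exact zero
  by default (`background_sd = 0`), so secretion calling is unambiguous in
  tests; half-normal background is opt-in since no background model is
  canonical for the instrument.
* **Patient batch effects** are additive on the log-MFI scale and shared
  across a patient's samples (SD 0.3 in the demo model) — matching the
  decision to correct between individual patients.
* **Planted outliers**: 1% of cells get one channel drawn uniformly in
  (3,001, 6,000) to exercise the >3,000 filter; intensity defaults keep
  natural draws far below the threshold, so planted outliers are the
  outliers.
* **Cohort layout.** The default design mirrors a 20-patient
  relapsed/refractory AML checkpoint-blockade cohort: all 20 with baseline
  PB, 16 with baseline BM, 10 with post-IO PB, 6 with post-IO BM, ~1,000
  cells per sample per subset.
* **The demo model** (`default_model()`) contains a quiescent population,
  a population cosecreting IFNg/TNFa/MIP-1b/IL8 enriched in responders'
  bone marrow, a regulatory population cosecreting IL4/IL10/IL13/TGFb1,
  and a negative age effect on IL2 intensity — the features the analysis
  layers are designed to detect.

`plant_da_shift()` and `plant_response_effect()` perturb the weight grid
and renormalize within condition; note the realized abundance ratio after
renormalization is smaller than the nominal fold change unless the
population is rare (for a population at weight 0.1, a 4-fold plant
realizes ≈ 3.1-fold).

What the simulator does **not** emulate: cytokine–cytokine correlation
beyond co-secretion structure, heavy-tailed MFI noise, plate/chip effects
distinct from patient effects, cell-size covariates, or kinetics. Passing
tests on simulated cohorts therefore demonstrate that the algorithms
recover the structure they model — not that real secretome data satisfies
that model.

# Numerical conventions and degenerate inputs

* Secretion calls use strict `>`; the outlier filter uses strict `>`.
* PCA signs are fixed by the largest-loading convention; kNN ties resolve
  by the (deterministic) search order; Leiden and UMAP are seeded.
* Zero-cell samples, all-zero neighborhoods, single batches, single
  clusters, constant covariates and zero-difference pairs are all flagged
  (`note` columns, attributes) rather than silently dropped or NaN'd.
* The full pipeline on a fixed seed is bit-reproducible; `run_all()`
  writes a manifest with MD5 checksums so reruns can be verified.

# Problem sizes used in the shipped checks

The package's cohort-scale checks (the acceptance script and the
heavier tests) run, as the package's own choice of demonstration scale:
PSI oracle equivalence on 1,000 random ≤20×5 instances; outlier-filter
recovery at 10,000 cells; DA recovery and null calibration at 12 samples
× 1,000 cells with k = 100 (100 permutation reps); clustering recovery at
2,400 cells; and derived-group response power over 100 simulated
16-patient cohorts of 120 cells per sample. These sizes recover the
planted truth with comfortable margins while keeping a full run in
minutes on one CPU.

# Known limitations

* The NB-GLM ignores within-patient pairing across timepoints (the design
  has a timepoint term only), mirroring the reference framework; a patient
  covariate is a natural extension.
* `derive_groups()` requires `k_groups` to be chosen; no gap statistic or
  silhouette sweep ships in this version.
* The batch-correction stage is contract-equivalent, not numerically
  equivalent, to any published implementation.
* Exclusivity percentages and DA statistics depend on k and the sampling
  proportion; these are exposed, logged in the manifest, and should be
  reported alongside results.
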