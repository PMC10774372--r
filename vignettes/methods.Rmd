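---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each stage of the
package, the assumptions they make, the default parameters, the design
of the synthetic-data generator, and known limitations. It is a methods
reference, not a tutorial; see the README for a worked example.

## The biological picture

The package targets tumors with a nodular/internodular architecture,
modelled on medulloblastoma with extensive nodularity. Six cell states
are represented throughout:

* `prolif_early_cgnp` — proliferating early granule-neuron-precursor-like
  cells, internodular;
* `early_cgnp` — post-mitotic early precursors, internodular;
* `migrating` — cells transitioning between zones;
* `differentiated` — neuronally differentiated cells filling the nodules;
* `astrocytic_like` — an astrocyte-like population at the nodule rims;
* `stromal_immune` — non-malignant stroma and immune cells.

The first four form the malignant differentiation lineage
(`lineage_states`); the first five are malignant.

## Synthetic tissue and expression

`simulate_tissue()` places non-overlapping circular nodules in a
rectangular field, defines three zones (nodular, a rim band of default
width 60 µm, internodular) and samples cell positions with a minimum
spacing of 16 µm. Each state has a per-zone propensity (for example
`differentiated` is concentrated in nodules, `prolif_early_cgnp` and
`early_cgnp` are internodular, `astrocytic_like` sits on the rim), so
compartment structure is planted, not emergent.

`simulate_expression()` draws negative-binomial counts. The per-cell,
per-gene mean is a product of

1. a gene baseline (log-normal across genes),
2. a state effect: on/off marker blocks for proliferation, astrocytic
   and stromal programs, and smooth sigmoid programs in a latent
   differentiation time `t` for the lineage states (so the early,
   migrating and differentiated programs rise and fall gradually —
   this is what makes pseudotime recovery a fair test),
3. a per-patient, per-gene log-normal batch factor (`batch_sd`,
   default 0.2),
4. a copy-number fold change for a planted gain (default: a 1.5× block
   of 300 contiguous genes on one chromosome, carried by the malignant
   cells of patient P1),
5. optionally a per-patient, per-gene log-normal factor applied only to
   malignant cells (`malignant_patient_sd`, default 0). This models
   patient-private tumor programs: in real cohorts malignant cells
   cluster by patient while normal cells co-cluster across patients.
   The pipeline sets it to 0.5 and keeps the technical batch factor at
   0.05 so that exactly this structure appears; module-level examples
   leave it at 0 so defaults remain patient-symmetric.

The generator returns the full ground truth (states, latent time,
copy-number carriers, batch factors), which the test-suite uses as
planted answers.

`simulate_spots_and_masks()` renders the spatial modality: transcript
spots with a Gaussian point-spread function (σ = 0.93 px), plus nucleus
label masks. `simulate_bulk_compartments()` mixes noise-free state
signatures with Dirichlet-sampled compartment proportions and
log-normal measurement and batch noise to produce paired
nodular/internodular bulk samples.

## Spatial single cells

`detect_spots()` is a difference-of-Gaussians detector: the image is
convolved at σ and 1.6 σ, local maxima of the difference above a
response threshold are kept. The default σ of 0.93 px matches the
rendered point-spread function; thresholds in the range 0.004–0.0086
are appropriate for unit-peak spots. `segment_nuclei()` thresholds the
image, computes a distance transform and applies watershed, dropping
regions under `min_area`. `assign_spots_to_cells()` assigns each spot
to the nucleus label under its pixel (spots on background are counted
as unassigned). `qc_filter_cells()` keeps cells with 5–100 transcripts
and nucleus areas of 90–2000 px, bounds inclusive.

## Expression core

`normalize_counts()` scales each cell to 10,000 counts and applies
`log1p`. `embed_and_cluster()` runs PCA (default 30 PCs), builds a
union-symmetrized kNN graph (default k = 20) and applies Louvain
community detection; `merge_similar_clusters()` merges connected
components of cluster pairs whose mean profiles correlate at 0.95 or
higher, the usual cleanup when Louvain over-splits homogeneous
populations. Markers are two-sided Wilcoxon tests of each cluster
against the rest with Benjamini–Hochberg adjustment.

`module_score()` uses expression-bin-matched control genes, so scores
are centered against genes of comparable abundance; a consequence worth
knowing is that population-wide shifts are absorbed by the controls, so
scores are interpretable as contrasts between cells, not as absolute
levels. `cell_cycle_phase()` scores S and G2M sets this way and calls
G1 when neither score is positive. `annotate_by_reference()` computes
Spearman correlations to reference state centroids and leaves cells
with a best correlation below 0.2 unassigned; annotation should be run
on an informative (marker) gene subset, since correlating over a large
background panel dilutes correlations below that floor even when the
best-matching state is correct.

`batch_adjust()` centers each gene within each patient (per-batch mean
removal). This removes additive patient effects but also removes real
patient-level biology; that is why the pipeline calls malignancy on
uncorrected data and integrates only for trajectory inference.

`tf_activity()` regresses each cell's expression on a gene-by-regulon
design and reports per-cell ordinary-least-squares t-values.
`overlap_test()` compares marker sets by chi-squared test, switching to
Fisher's exact test when expected counts fall below 5.

## Malignancy

`call_malignant_clusters()` applies the patient-composition rule: a
cluster whose largest patient fraction is at least 0.95 (inclusive) is
called malignant. The rule presumes the cohort structure described
above — it is applied to clusters of uncorrected expression.

`infer_cnv_profiles()` computes log-residuals against the mean of a
declared normal reference (at least 20 cells), clips them to ±1,
smooths with a 101-gene running mean strictly within chromosomes
(shrinking the window with a warning on short chromosomes), and
subtracts each cell's median. With clipping disabled the reference mean
is exactly zero by construction; with the default clip the sparse
residual distribution is skewed and the centering is approximate.
`cnv_block_score()` averages the profile over a gene block;
`cnv_burden()` is the mean squared profile per cell.

## Trajectory

`lineage_graph()` connects cluster centroids in PC space by a minimum
spanning tree (ties broken lexicographically so results are
deterministic) and enumerates root-to-leaf paths. The root is the
cluster with the highest mean S + G2M score (`pick_root_cluster()`),
reflecting that the lineage starts in the proliferating state.
`pseudotime()` orthogonally projects each cell onto the piecewise-linear
path of its nearest lineage and reports the arc length from the root,
clamped to the path ends.

## Compartment bulks

`de_between_compartments()` fits `expression ~ compartment + patient`
per gene by ordinary least squares — the patient term absorbs paired
batch shifts — and calls significance only when both the absolute log2
fold change exceeds 0.5 and the Benjamini–Hochberg adjusted p-value is
below 0.05. Fully confounded designs are refused.

`signature_enrichment()` is a single-sample weighted
Kolmogorov–Smirnov statistic (signed maximum deviation) with rank
weighting exponent τ = 0.25. Rank weighting biases scores of random
sets slightly positive; the statistic is therefore meant for ranking
samples and sets, not as a calibrated null statistic (at τ = 0 the
statistic is unbiased and antisymmetric).

`deconvolve_bulk()` normalizes state signatures to unit column sum,
solves non-negative least squares per sample and renormalizes the
coefficients to the simplex, which also makes results invariant to
sample scaling. `composition_statistics()` runs Welch t-tests for
two-level covariates and Spearman correlations for numeric ones,
returning `NA` rather than failing on degenerate inputs.

## Spatial statistics

`build_spatial_graph()` offers a Delaunay triangulation (Bowyer–Watson,
implemented in the package; collinear inputs fall back to a kNN graph
with a warning) and a union-symmetrized kNN graph. Edges longer than 4×
the median nearest-neighbor distance are pruned, which removes the long
convex-hull edges to outliers.

`colocalization_enrichment()` scores each type pair as
`log2((observed + 1) / (mean permuted + 1))` over graph edges, with
doubled-tail permutation p-values (adding one to numerator and
denominator). Doubled-tail p-values are discrete and slightly
conservative, never anti-conservative.

`compartment_map()` builds a kernel density estimate of an anchor state
(`differentiated` by default; bandwidth 75 µm on a 2 µm grid), applies
Otsu's threshold and labels connected components as nodules; every cell
is then assigned nodular/internodular by its grid cell. The kernel σ is
capped so the blur brush fits small grids (with a warning). The Otsu
boundary sits close to, but not exactly on, the true nodule edge, so
per-type compartment fractions are recovered well for zone-restricted
states while states that live exactly on the rim are split between the
two sides in a boundary-sensitive way.

## Pipeline and reproducibility

`run_config()`/`read_run_config()` validate every key (unknown keys,
including nested ones, are errors) and overlay partial section lists
over defaults. Each stochastic stage receives a sub-seed derived by
hashing the global seed with the stage name (all sub-seeds below
2^31), so toggling one stage never changes another stage's draws, and
identical configs give byte-identical outputs. `run_pipeline()` runs
simulate → cells → cluster → malignancy → trajectory → spatial →
deconvolve and writes a JSON report of seeds, parameters and stage
summaries.

## Limitations

* The copy-number model detects broad planted gains; it is not a
  breakpoint caller and inherits the usual limits of expression-based
  inference (reference choice, clipping asymmetry).
* The malignancy rule depends on the cohort structure it encodes; in
  data where normal cells also separate by patient (strong technical
  batch), it will over-call, as it has no expression-level notion of
  malignancy on its own. Combining it with copy-number burden is
  recommended.
* Pseudotime is a piecewise-linear projection; it recovers the order of
  a smooth lineage but not branch-point uncertainty or velocity.
* The permutation test conditions on the graph and type frequencies;
  p-values are conservative for rare types.
* The generator plants idealized geometry (circular nodules, isotropic
  kernels); it is designed to make ground truth unambiguous, not to
  reproduce tissue morphology in detail.
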