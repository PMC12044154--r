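---
title: "Persistent local relationship signatures: model and design notes"
author: "winsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent local relationship signatures: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiplexed tissue imaging and spatial transcriptomics deliver tables of
segmented cells — coordinates plus a cell-type label or a marker vector —
for cohorts of patient samples. Two samples with identical cell-type
*composition* can be organised very differently in space, and that
organisation (which types co-locate, avoid each other, or regulate each
other locally) often carries the clinically relevant signal. `winsig`
learns an unsupervised, explainable representation of that organisation:
it describes each small tissue patch not by what it contains but by the
*predictive relationships* between its cells, finds patches with recurring
relationship patterns across a cohort, and uses their per-sample
frequencies for patient stratification.

## The model

### Views

Each cell is described by two views, computed on the **full sample** before
any windowing so that neighbourhoods crossing window borders are intact:

* **intraview** — the cell's own state: a one-hot cell-type vector, or its
  marker-abundance vector;
* **paraview** — its spatial context: in cell-type mode the sum of the
  one-hot vectors of the `k = 10` nearest neighbours (self excluded,
  distance ties broken by ascending cell index); in marker mode the
  RBF-weighted sum `sum_{j != i} exp(-d_ij^2 / l^2) m_j` with length scale
  `l = 100` coordinate units. Units are whatever the input coordinates use
  (pixels or micrometres); `l` and the window size are interpreted in those
  native units.

### Windowed multi-view models

Each sample is covered by square windows of side `s` sliding with stride
`s(1 - o)` (`o = 0.5` by default), anchored at the sample's minimum x/y.
Intervals are half-open with a right-closed final row/column, so at
`o = 0` the windows exactly partition the bounding box. Windows with fewer
cells than intraview features are flagged invalid and not modelled.

Within a valid window, every intraview feature in turn becomes the target
of a multi-view model: one random forest per view (100 trees, `sqrt(f)`
features per split, impurity importance = total reduction of target
variance), whose out-of-bag predictions are fused by an L2-regularised
linear meta-model with intercept. In cell-type mode only the paraview is
modelled — predicting a cell's one-hot type from its own type is trivial —
so the gain in variance explained equals the total variance explained. In
marker mode the intraview forest predicts each marker from the cell's
other markers, and the gain is `R2_multi - R2_intra`.

The per-(target, view) raw importances `I` are standardised and weighted
by the view contribution,

    M_j = (I_j - mean(I)) / sd(I) * (1 - p),

where `p` is the two-sided t-test p-value of the view's coefficient in an
unregularised linear refit of the fusion (clamped to [0, 1]; degenerate
views get `p = 1`). A zero-spread importance vector maps to zeros.

### Signatures, graph, communities, persistence

The window's signature concatenates `M` over all (view, predictor, target)
triples, zeroes every entry of targets whose gain falls below 1%, and
clamps negatives to zero, so all windows share one nonnegative coordinate
system. Cosine similarities between nonzero signatures form a graph whose
edges below a cutoff are dropped; Leiden community detection (modularity
objective, seeded) labels the windows. A cluster is *persistent* when it
occurs in at least `min(ceiling(0.10 S), 5)` distinct samples — the two
branches of the criterion are read disjunctively, so whichever is smaller
binds. Windows of dropped clusters are removed from the representation.

### Downstream

Each sample is represented by the frequency of its persistent windows per
persistent cluster (denominator: the sample's persistent windows; samples
with none get a zero vector and a warning). An *unregularised* logistic
model, evaluated by seeded stratified 10-fold cross-validation with the
macro-averaged AUROC computed on the concatenated out-of-fold scores,
quantifies how much clinical signal the representation carries. Cluster
relevance is the signed model reliance
`sMR_i = sgn(beta_i) L(f, D_perm(i)) / L(f, D)` with `L = 1 - AUROC`,
averaged over 100 independent permutations of feature i; the stored fold
models are reused, never refitted, and a zero loss is floored at
`1/(2 n)` with a warning.

Clusters are explained three ways: per-target variance-explained profiles
with mean importances filtered at one standard deviation above the mean
(0.5 for the marker-mode paraview) and predictor-target sign correlations
pooled over member-window cells; spatial contiguity via Moran's I of the
cluster indicator on the window grid (binary 8-neighbour weights,
analytic randomisation mean/variance, one-sided upper tail,
Bonferroni-corrected per cluster across samples then BH-corrected across
clusters); and a multivariate hypergeometric null for how many distinct
samples a cluster of `W` windows would span under uniform draws without
replacement, summarised by its median and 10/90% quantiles (inverse-ECDF
quantiles; 10,000 draws by default).

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `paraview_k` | 10 | neighbours | cell-type paraview size |
| `paraview_l` | 100 | coordinate units | RBF length scale |
| `window_size` | 200 | coordinate units | selected per task (see below) |
| `overlap` | 0.5 | fraction | stride `s(1-o)` |
| `n_trees` | 100 | trees | forest size |
| `similarity_cutoff` | 0.8 | cosine | selected per task |
| `leiden_resolution` | 1.0 | — | selected per task |
| `persistence_fraction` / `count` | 0.10 / 5 | samples | disjunctive rule |
| `gain_threshold` | 0.01 | R² | signature filter |
| `ridge_lambda` | 1e-3 | — | fusion penalty, standardized scale |

The window size, similarity cutoff and Leiden resolution are not fixed
constants of the method but are selected per task by their
cross-validated stratification performance; `sweep_clustering()` performs
the cutoff/resolution grid search cheaply (window models are reused), and
the reproduction script selects the window size over a small grid
(`{200, 300, 400}`) the same way. Performance is concave in window size —
too-small windows starve the forests, too-large ones average local
patterns away — so a small grid around the scale of the expected biology
suffices.

## Numerical choices

* **Honest window-level R².** The fusion's variance explained is estimated
  by 10-fold cross-validation inside the window (ridge coefficients refit
  without each fold, held-out predictions concatenated), so pure-noise
  targets sit at or below zero rather than inheriting the ~1/n in-sample
  optimism that would flood the 1% gain filter. The meta-model
  *coefficients* come from the in-sample ridge fit, for which the
  multi-view R² provably cannot fall below the intraview-only R² (up to
  the tiny penalty), and the tests assert exactly that property.
* **Out-of-bag view predictions** feed the fusion so its weights are not
  optimistically biased; out-of-bag values that are undefined (a cell
  in-bag in every tree) fall back to the window mean.
* **Determinism.** All randomness derives from one seed through named
  substreams (per window, per forest, per stage), forests run
  single-threaded with fixed seeds, and Leiden is seeded; two runs of the
  full pipeline on the same cohort are bit-identical.
* **Degenerate inputs.** Zero-variance targets are recorded with zero
  variance explained and zero importances; all-zero signatures are
  excluded from the graph and labelled unassigned; constant Moran
  indicators return not-applicable; a zero stratification loss is floored
  before the reliance ratio.
* **Ties.** KNN distance ties break by ascending cell index; cluster
  labels are renumbered by descending window count; quantiles of discrete
  null draws use the inverse-ECDF definition.

## The synthetic cohort generator

`simulate_cohort()` provides the study conditions every claim is tested
under: 10 + 10 samples of 800x800 units with Poisson(1500) cells placed
uniformly, 8 cell types at uniform background frequencies, and one planted
attraction niche — disc-shaped regions (radius 150) in which the
probability that a cell is type T2 is tilted by
`exp(strength * min(n_A, 3))` given its count of type-T1 neighbours within
40 units, realised by three seeded Gibbs-style sweeps. The tilt is
asymmetric (T2 is enriched *near* T1; T1 keeps its background frequency),
which is what makes the relationship locally predictable rather than a
uniform compositional shift. Strength 3 is the "strong" default;
strength 0 reduces exactly to background, and measured enrichment is
monotone in strength (tested).

Each sample carries three fixed candidate niche sites (jittered lattice
positions); each site is occupied independently with the condition's
prevalence (0.9 versus 0.1 by default). Conditions therefore differ only
through a *graded niche load* (0-3 instances), mirroring the way real
condition-discriminative niches recur within tissues and appear as
cluster-frequency differences; with a single all-or-nothing presence draw,
even perfect niche detection would cap the expected AUROC at 0.90, leaving
no room to observe detection quality.

In marker mode, types map to archetypal marker profiles plus fixed linear
intra-cell dependencies, one RBF-coupled neighbour dependency, and
Gaussian noise (sd 0.1), clamped at zero.

What the generator does **not** emulate: segmentation errors, imaging
noise models, batch effects, irregular tissue boundaries, or
density gradients. Passing tests on this generator therefore show that the
pipeline recovers planted neighbour-conditional structure under realistic
sizes and noise — not that it is robust to the full messiness of real
cohorts.

For niche-recovery scoring, a window belongs to a niche's footprint when
at least 25% of its cells lie in the niche region. With 50% overlap each
niche cell is seen by about four windows, so windows genuinely carrying
the relationship outnumber majority-niche windows roughly two to one; a
majority-label footprint would cap even a perfect detector's Jaccard near
0.47. The per-sample ARI, by contrast, uses the majority label per window.

## Problem sizes used by the tests

The test suite runs the full pipeline on the default 20-sample cohort
(~1280 windows) for the determinism and positive-control checks, on ten
12-sample, 400-unit, 5-type cohorts for the negative control, and on
3-6-sample cohorts for unit-level checks; oracle comparisons (brute-force
KNN/RBF/Moran/hypergeometric enumerations) use 10-40 cells or 36 grid
cells. These sizes were chosen so each property is measured at the
smallest scale at which it is meaningful.

## Known limitations

* Dense pairwise distances bound the view computation at roughly 10^4-10^5
  cells per sample; larger samples need blocking or subsampling upstream.
* The signature standardises importances within each (target, view) pair,
  so a barely-informative target contributes as much vector mass as a
  strong one once it passes the gain filter; with a single planted
  relationship this is the main source of cross-window signature noise,
  and it is why the similarity cutoff must be selected per task rather
  than fixed.
* Cross-validated AUROC on 20-30 samples has high variance; reported
  values should be read with that in mind, as in any small-cohort study.
* Folds are stratified at the sample level; with multiple samples per
  patient, grouping by patient would be the right unit (not implemented).
* The functional-context transforms of the wider multi-view family
  (pathway activities, ligand-receptor views) are out of scope; the view
  composition here is exactly intraview + paraview.
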