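# winsig — persistent local relationship signatures for spatial omics

`winsig` learns an unsupervised, explainable representation of tissue
organisation from segmented-cell tables (multiplexed imaging or spatial
transcriptomics: x/y centroids plus a cell-type label or marker vector per
cell) and uses it for patient stratification. It is aimed at translational
spatial-omics analysts with cohorts of tens of samples and binary clinical
labels (responder/non-responder, progressor/non-progressor).

Instead of describing tissue patches by their composition, `winsig`
describes them by their **local predictive relationships**. Each sample is
decomposed into overlapping square windows; within every window each
feature *i* (cell type or marker) is modelled from the views of the other
features,

    Y_i = a_I + a_0 F_0(intraview) + sum_v a_v F_v(view_v),

with one random forest `F_v` per view and an L2-regularised linear fusion
of their out-of-bag predictions. The views are the **intraview** (the
cell's own one-hot type or markers) and the **paraview** (the summed
one-hot types of its 10 nearest neighbours, or the RBF distance-weighted
marker sum `sum_j exp(-d_ij^2/l^2) m_j`). Each forest's impurity
importances are standardised and weighted by the view contribution,

    M_j = (I_j - mean I) / sd I * (1 - p_v),

and concatenated into the window's **importance signature** after zeroing
targets below 1% gain in variance explained and clamping negatives.
Windows from all samples are connected by cosine similarity above a
cutoff, clustered by Leiden community detection, and clusters present in
fewer than `min(ceiling(0.10 S), 5)` samples are discarded (**persistence
criterion**). Each sample is then a frequency vector over persistent
clusters; an unregularised logistic model evaluated by stratified 10-fold
CV (macro-AUROC on concatenated out-of-fold scores) measures the clinical
signal, and each cluster is explained by signed model reliance
`sMR = sgn(beta) L_perm / L` (`L = 1 - AUROC`), per-target
variance-explained profiles with sign correlations, Moran's I contiguity
on the window grid, and a multivariate hypergeometric null for its
sample spread.

The package also ships the comparison representations (global
composition, whole-sample relationship representation, window composition
clustering) and a seeded synthetic-cohort generator with planted
attraction/avoidance niches and full ground truth.

## Worked example

The default synthetic cohort plants one strong attraction niche (type T2
enriched near T1 inside disc-shaped regions) at per-sample site prevalence
0.9 in condition 1 versus 0.1 in condition 2; the run takes a few minutes
on one CPU.

```r
library(winsig)

sim <- simulate_cohort(cohort_spec(seed = 42))   # 10 + 10 samples
fit <- winsig(sim$cohort, winsig_config(mode = "celltype", seed = 42))
print(fit)
#> <winsig> fit on 20 samples (mode: celltype )
#>   windows: 1280 total, 1280 valid, 977 assigned
#>   clusters: 330 detected, 51 persistent
#>   window size 200 with overlap 0.5 ; cosine cutoff 0.8

# per-task selection of the two clustering parameters, as the method
# prescribes (grid search scored by cross-validated macro-AUROC)
sw <- sweep_clustering(fit, seed = 1)
sw$best
#>   cutoff resolution n_persistent auroc
#> 9    0.5          1            8  0.87

st <- stratify(sw$fit, seed = 1)

rec <- score_recovery(sw$fit, sim$truth)
rec$niche_jaccard
#>    niche n_windows best_jaccard cluster
#> 1 niche1       386    0.4989293       1

smr <- signed_model_reliance(st, n_perm = 100, seed = 1)
round(sort(abs(smr), decreasing = TRUE)[1:3], 2)
#>  cl1  cl3  cl2
#> 5.20 3.27 2.76
```

`print(fit)` reports how many windows were modelled and how many window
clusters survived the persistence filter (at 20 samples the threshold is
presence in 2 samples). The sweep selects cosine cutoff 0.5 and Leiden
resolution 1, where the cluster-frequency logistic model reaches a
cross-validated macro-AUROC of 0.87. `score_recovery()` compares the
clustering with the generator's ground truth: the planted niche's window
footprint is matched by persistent cluster 1 (Jaccard 0.50), and that same
cluster carries by far the largest signed model reliance (|sMR| = 5.2), so
the stratification is explained by the pattern that was actually planted.
Window-size selection over a small grid (for example `{200, 300, 400}`)
works the same way and is what `scripts/acceptance.R` does.

Each cluster can then be decomposed and tested:

```r
ex  <- explain_cluster(fit, cluster = 1)  # relationships behind a cluster
mor <- moran_contiguity(fit)              # spatial contiguity tests
fn  <- frequency_null(fit)                # observed vs expected sample spread
```

A thin command-line front end with subcommands (`simulate`, `views`,
`windows`, `model`, `cluster`, `represent`, `classify`, `explain`,
`baseline`) lives at `inst/cli/winsig.R`; every stage writes delimited
text plus a JSON run-metadata sidecar.

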