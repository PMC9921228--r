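---
title: "Joint connectivity-matrix ICA: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint connectivity-matrix ICA: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Connectivity-matrix ICA treats a space-by-space connectivity matrix `C` as a
mixture of rank-1 terms,

    C = R S = sum_k R_k S_k ,

with independent spatial sources `S` over a seed domain (gray-matter voxels,
"Region A") and connectivity maps `R` over a target domain ("Region B":
gray matter again for functional connectivity, white matter for structural
connectivity). The sources carry the independence assumption; the maps do
not — each `R` column is mathematically a seed-based connectivity profile of
its source and is free to overlap other maps.

**Functional branch.** For one subject, voxel time courses are temporally
normalized (each voxel column centered, unit sample sd, `n − 1` denominator;
zero-variance voxels are zeroed, kept in the mask for alignment, and
reported). With the SVD `X̃ = V Σ U'`, the voxel-pair correlation matrix is

    C = X̃' X̃ / (T − 1) = U Σ² U' / (T − 1) ,

so the spatial eigenbasis of `C` is available without ever forming the
V × V matrix. Spatial ICA runs on the whitened top-`c` spatial
representation `√V · U_c'` (whitened exactly: its Gram matrix is the
identity), giving

    S = W U_c' ,    R = U_c Σ_c² W⁻¹ / (T − 1) ,

and `R S` equals the rank-`c` eigen-truncation of `C` for any invertible
`W` — this identity is the package's correctness contract for the shortcut
and is tested against the explicit-matrix route (build `C`, eigendecompose,
run the same-seeded ICA) on instances of a few hundred voxels. The printed
placement of the `1/(n−1)` factor in the source formula is ambiguous; it is
implemented on `R`, the only reading under which `R S` reproduces the
correlation matrix.

**Structural branch.** The fiber-count matrix (gray × white voxels,
nonnegative) is decomposed directly: `C' = V Σ U'` truncated at rank `r`,
sources over gray voxels from `U`, tract maps from `V Σ`. No `1/(n−1)` and
first-power singular values, because no cross-product is involved. An
optional `log1p` transform is offered for the heavy-tailed count
distribution; the default is no transform.

## Group model and joint fusion

Two PCA stages per modality: (1) subject-level truncated SVD at rank
`subject_r`; (2) group-level SVD of the row-concatenated subject
representations `Σ_k U_k'` at order `m_per_modality`, recording each
subject's partition `Ṽ_k` of the group co-basis. The two modality bases are
then concatenated along the gray-voxel dimension as `√V · U_group'` blocks.
Because each block's rows then have exactly unit variance, both modalities
enter the joint ICA with an equal share regardless of the very different
numerical scales of correlations and fiber counts — this block-whitening
*is* the balancing step, applied at the PCA stage rather than to raw data.
The stacked matrix is whitened jointly (its rows correlate across blocks)
and ICASSO-stabilized spatial ICA estimates `c = m_FC + m_SC` sources
(symmetric model). Aggregate sources are scaled to unit variance over gray
voxels; the mixing matrix `A = W⁻¹` absorbs the scale.

**Back-reconstruction.** The printed group back-projection formula contains
a non-invertible partition inverse; the package implements the standard
GICA pseudo-inverse chain. With `W_m` the demixing columns of modality block
m, `Σ̃_m` the group singular values and `Ṽ_k` the subject partition:

    S_k = N √V  W_m Σ̃_m⁻¹ Ṽ_k'  (σ̃_k ũ_k')          (c × V_gm)
    R_k = P_k · pinv(K_k),   K_k = N √V W_m Σ̃_m⁻¹ Ṽ_k'  (V_B × c)

where `P_k` is the subject's connectivity co-factor (`Ũ_k Σ̃_k/(T−1)` for
FC, the white-voxel basis `Ṽ_k` for SC). Two contracts define correctness:

1. *Mean consistency*: the subject-mean of `S_k` equals the aggregate
   sources restricted to that modality's contribution **exactly**, by the
   SVD partition identity `Ṽ' G = Σ̃ Ũ'` (observed ≈ 1e−15 relative).
2. *Reconstruction tightness*: `R_k S_k` reproduces the subject's
   connectivity matrix at the PCA truncation floor. The floor is evaluated
   at the composite rank the two-stage chain retains for that subject
   (the rank of `K_k`): a subject whose r-th own direction is orthogonal to
   the group subspace — a strong modality-specific source — has an exactly
   rank-deficient partition, so the rank-`r` floor is unattainable by
   construction and the honest reference is the rank the chain kept.

## ICA engine and stability conventions

The default unmixing algorithm is Infomax: full-batch natural-gradient
updates with a logistic nonlinearity and bias term, learning rate
`0.015/log(c + 2)`, halved on numerical blow-up with a restart from the
seeded initial point; convergence when the relative weight change drops
below `tol` (default 1e−6, cap 2000 iterations; non-convergence is flagged,
not fatal). The logistic contrast suits the super-Gaussian, sparse spatial
sources this pipeline targets; a deflationary fastICA with tanh contrast is
available behind a flag (and is the right choice for sub-Gaussian sources,
which plain logistic Infomax cannot separate — extended Infomax is out of
scope). Inputs must be whitened (`ZZ'/m = I` within 1e−6, enforced).

Every run ends with a symmetric decorrelation `W ← (WW')^{−1/2} W`, so
source rows are exactly orthogonal on whitened input. This pins two
conventions: run-to-run component similarity is the absolute *uncentered
cosine* (sign- and permutation-invariant), and in the degenerate case where
all reruns are identically seeded, intra-cluster similarity is exactly 1 and
inter-cluster similarity exactly 0, so every cluster-quality index equals
1.0 exactly rather than approximately.

ICASSO-style stability: `n_runs` reruns (20 by convention) with seeds
`base_seed + run index`; all components pooled and clustered by
single-linkage (the minimum-spanning-tree linkage) on `1 − |cosine|` into
`c` clusters; cluster quality = mean intra-cluster minus mean inter-cluster
similarity, clipped to [0, 1]; the exemplar of each cluster is its
centrotype (member with maximal total intra-cluster similarity); the best
run maximizes the summed similarity of its components to the `c`
centrotypes, ties resolved to the lowest run index.

Component alignment for all recovery tests is an optimal one-to-one
assignment maximizing summed |Pearson correlation| (a hand-written
Hungarian algorithm, verified against exhaustive permutation search), with
sign flips to positive correlation; zero-variance rows are excluded and
reported.

## Component analytics

- **Loadings** are the columns of `A = W⁻¹` partitioned by modality block
  (the literature says "loadings" without fixing the matrix; this is the
  declared interpretation). The contribution ratio of component j is
  `mean |A_FC[, j]| / (mean |A_FC[, j]| + mean |A_SC[, j]|)`; FC and SC
  contributions sum to 1 exactly. Components with a ratio in [0.2, 0.8]
  (inclusive, per the "no more than 80% and no less than 20%" rule) are
  shared. An `exclude` argument implements the manual artifact screen; no
  automated artifact classifier is attempted since no criteria are defined
  for one.
- **Explained variance** per modality uses squared column norms of the
  mixing blocks (valid because sources are orthogonal unit-variance rows);
  components are sorted by the across-modality mean, ties stable by index.
- **Thresholding** retains voxels above the map's own mean plus `k` sd:
  `k = 3` for source maps, `k = 2` for connectivity maps (which are
  spatially less sharp). Applied to one-sample t-maps across subjects
  (`t = mean/(sd/√n)`, zero-sd voxels flagged and set to 0). No
  multiple-testing correction — the rule is a visualization/ROI convention,
  not an inference procedure. ROIs are nested by construction:
  ROI(k=3) ⊆ ROI(k=2).
- **Atlas labeling** uses containment overlap, `100·|ROI ∩ label|/|ROI|`,
  assigning the maximum-overlap label (ties to the lowest id) regardless of
  orientation. Containment rather than Dice is deliberate: a tract ROI is
  labeled by its best atlas match even when that match is weak (single-digit
  percentages against a non-exhaustive atlas), which a symmetric index would
  suppress. Background counts toward the total so percentages sum to 100.

## The synthetic cohort generator

The generator is the package's test bed and defines its study conditions.
It emulates exactly the structure the model assumes:

- `k_shared + k_fc_only + k_sc_only` compact Gaussian gray-matter blobs
  (unit maximum, support at the `exp(−2)` isocontour, ≤ 5% pairwise support
  overlap by rejection sampling with a capped attempt budget → capacity
  error). Default grid 12×12×6 (864 voxels).
- Functional expression `M_fc = S_true + 0.3 × partner`, the partner being a
  disjoint "network partner" blob — so FC networks extend beyond the source.
- Structural expression `B_sc`: elongated tract-like segments with Gaussian
  cross-section on the white-matter grid (default 10×10×6), placed
  near-disjointly (≤ 5% overlap, best-of-200 rejection). Disjointness keeps
  the SC gray-side eigenbasis aligned with individual sources — the
  unambiguous recovery target the generator exists to provide.
- Subject fMRI: `X = τ (w ∘ M_fc) + ε`, latent courses τ i.i.d. standard
  normal (so the implied voxel covariance is exactly
  `M' diag(w²) M + σ² I`), white noise `σ = 0.2` by default, `T = 300`.
- Subject SC: Poisson counts with mean
  `mean_count · Σ_k w_k S_k' B_k` (`mean_count = 10`).
- Subject strengths: lognormal (sdlog 0.2) around 1 for shared sources;
  modality-specific sources are expressed at 0.45 relative strength. This
  asymmetry is a study-condition choice, fixed a priori from a dimensional
  argument: the validation cohort uses a symmetric joint order c = 8, i.e.
  m = 4 retained directions per modality against 6 expressed sources, which
  is only a well-posed recovery problem when the shared sources dominate
  each modality's leading variance directions. The 0.45 factor (≈ 20%
  relative variance) leaves that ordering robust to the residual spread in
  map norms from voxel discretization.

What the generator does *not* emulate: hemodynamics, autocorrelated BOLD
noise, motion or physiological artifacts, realistic tract geometry or
count dispersion beyond Poisson, and registration error. Passing tests
therefore demonstrate the correctness of the algorithmic chain under its
own assumptions, not performance on real MRI data.

One consequence of the method's own normalization is worth stating: after
temporal normalization every voxel has unit variance, so the recoverable
spatial map is the planted map *divided by each voxel's time-course sd* —
flattened on its support. Recovery oracles in the tests compare against
this normalized-space map where the flattening matters (noiseless
single-subject recovery, subject network maps); at the default noise level
the group-level aggregate sources still match the raw planted maps at
|corr| ≥ 0.97.

## Numerical conventions

- Sample-sd (`n − 1`) convention everywhere.
- Factor sign convention: every spatial basis column is oriented so its
  maximum-magnitude entry is positive (deterministic across platforms);
  ICA component signs are pinned the same way in alignment.
- All randomness flows from explicit integer seeds through `withr::with_seed`;
  per-subject and per-rerun seeds are derived deterministically from a
  master seed and stay below 2³¹. Identical configuration + seed reproduces
  every reported number to better than 1e−10 (bitwise in practice).
- The joint whitener refuses rank-deficient input (smallest eigenvalue
  below 1e−10 of the largest), pointing at an over-large group order.
- Model serialization is RDS plus a JSON provenance manifest (config hash,
  seed, package version); connectivity matrices interchange as MatrixMarket,
  volumes as NIfTI-1 (float32, round-trip tested to 1e−6 relative).

## Default orders and problem sizes

Production-scale defaults follow the method's conventions (`subject_r = 40`,
`m_per_modality = 30`, `c = 60`, 20 ICASSO reruns) and are fully
configurable. The validation suite and the acceptance script run the
generator's study conditions at desk scale — 10 subjects, 864 gray voxels,
600 white voxels, `subject_r = m_per_modality = 4`, `c = 8` — chosen so the
whole suite completes in a few minutes on one CPU while exercising every
code path at the sizes where the exact contracts (mean consistency,
truncation floors, route equivalence) are checkable to machine precision.
`subject_r = m_per_modality` is deliberate: with equal orders the
back-reconstruction chain is exact and the reconstruction ratio sits on the
truncation floor, which is the regime the tightness contract presumes.

## Known limitations

- Plain logistic Infomax will not separate sub-Gaussian sources; use the
  fastICA flag there. Extended Infomax and automatic order selection
  (MDL/AIC) are out of scope.
- The balancing step equalizes block variance, not spatial-distribution
  differences between modalities; with strongly asymmetric data the
  decomposition remains biased toward one modality — an intrinsic property
  of the approach, surfaced by the contribution ratio rather than corrected.
- Grid matching between modalities (resampling/registration) is assumed done
  upstream; masks must share grids with the data they index.
- DICOM and surface formats are not handled; NIfTI-1 volumes only.
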