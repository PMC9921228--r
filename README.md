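# jcmica — joint connectivity-matrix ICA for multimodal brain connectivity

`jcmica` fuses two views of brain connectivity into one decomposition. From
resting-state fMRI it takes voxel-wise **functional connectivity** (FC, the
temporal correlation of every gray-matter voxel pair — never built
explicitly); from diffusion-MRI tractography it takes **structural
connectivity** (SC, fiber streamline counts between gray-matter and
white-matter voxels). Connectivity-matrix ICA (cmICA) factorizes a
connectivity matrix as

    C = R S,        C = sum_k  R_k S_k

where the rows of `S` are independent gray-matter spatial sources (cortical
parcels) and the columns of `R` are each source's connectivity map — a
functional network for FC, a white-matter tract for SC. The joint variant
concatenates both modalities along the target-voxel dimension after
per-modality PCA whitening (so neither modality's variance dominates) and
extracts gray-matter sources *shared* by structure and function, together
with the tract and network linked to each parcel, in one estimation.

For FC the package never forms the voxel-by-voxel matrix: with temporally
normalized data `X̃ = V Σ U'`, the correlation matrix is
`C = U Σ² U' / (n−1)`, so spatial ICA runs on the reduced `U'` directly
(`S = W Ũ'`, `R = Ũ Σ̃² W⁻¹ / (n−1)`). Group analysis uses a second,
group-level PCA per modality and GICA back-reconstruction
(`S_k = N √V W_m Σ̃⁻¹ Ṽ_k' σ̃_k ũ_k'`) for subject-specific maps. ICA runs
are stabilized ICASSO-style (20 seeded reruns, single-linkage clustering of
components, centrotype-based best-run selection). Components are screened by
the modality **contribution ratio** (mean absolute mixing loading per
modality block): components with 20–80% FC contribution count as shared.
Source maps are thresholded at `μ + 3σ`, connectivity maps at `μ + 2σ`, and
thresholded tract ROIs are named by maximum overlap against a labeled atlas.

The audience is neuroimaging methods researchers who want a data-driven,
atlas-free multimodal parcellation, plus a fully synthetic test bed: the
package ships a cohort generator that plants known shared / FC-only /
SC-only sources in both voxel time series and Poisson fiber-count matrices,
so every stage of the pipeline is verifiable without access to restricted
clinical data.

## Worked example

```r
library(jcmica)

truth  <- make_ground_truth(seed = 1)      # 4 shared + 2 FC-only + 2 SC-only
cohort <- simulate_cohort(truth)           # 10 subjects, T = 300, Poisson SC
model  <- fit_joint_cmica(cohort$fmri, cohort$sc,
                          subject_r = 4, m_per_modality = 4,
                          icasso_runs = 10, seed = 1)
model
#> <joint_cmica> 8 components | 10 subjects | 864 gray voxels | min stability: 0.927

component_summary(model)
#>   component variance_fc variance_sc contribution_fc shared spatial_similarity
#> 3         3      0.1692    0.247942           0.538   TRUE              0.793
#> 6         6      0.1531    0.248718           0.506   TRUE              0.733
#> 2         2      0.1230    0.247157           0.507   TRUE             -0.774
#> 5         5      0.1183    0.245809           0.541   TRUE             -0.780
#> 4         4      0.1304    0.005657           0.884  FALSE             -0.780
#> 7         7      0.1270    0.003806           0.892  FALSE             -0.774
#> 8         8      0.0981    0.000639           0.939  FALSE             -0.740
#> 1         1      0.0809    0.000272           0.953  FALSE             -0.797

align_components(model$aggregate_S, truth$S_true)$correlations[truth$shared_ids]
#> [1] 0.999 0.991 0.998 0.986
```

Reading the table: components are sorted by mean explained variance;
`contribution_fc` is the FC share of each component's mixing loadings, so
the four components near 0.5 are expressed in both modalities and pass the
20–80% shared screen (`shared = TRUE`) — exactly the four planted shared
sources, each recovered with |correlation| ≥ 0.986 against its ground-truth
map. The remaining components load almost entirely on the FC block
(`contribution_fc > 0.88`): they capture FC-only structure (the "network
partner" regions of the generator) and are correctly excluded.
`spatial_similarity` is the Pearson correlation between the two modalities'
group-averaged source maps; its sign is arbitrary per component (ICA sign
indeterminacy), the magnitude is what matters.

Subject-level maps and labeling:

```r
maps  <- back_reconstruct_all(model, "SC")       # per-subject S_k and R_k
t_map <- tstat_map(t(sapply(maps, function(m) m$R_k[, 3])))
roi   <- threshold_map(t_map, 2)                 # mu + 2 sigma for R maps
# atlas_overlap(devectorize(as.numeric(roi), truth$wm_mask) > 0, atlas)
```

A file-based pipeline (NIfTI volumes, MatrixMarket count matrices, TSV
manifest) is available through `cmd_simulate()`, `cmd_fit()`, `cmd_report()`
and the thin CLI wrapper `inst/cli/jcmica.R` with subcommands
`simulate | fit | report`.

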