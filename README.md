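# connectoscope

Resting-state fMRI group analysis in R: voxelwise activity metrics, a
90-node functional connectome with graph topology, covariate-adjusted group
statistics, and multi-kernel SVM classification — plus a synthetic BOLD
cohort generator with planted ground truth, so the entire pipeline is
testable without access to clinical data.

## Who this is for

Case-control resting-state studies (patients vs. matched controls) commonly
ask three questions: *where* does spontaneous activity differ (voxel
metrics), *how* is the functional network reorganized (graph topology), and
*can the connectome discriminate the groups* (classification with stable,
interpretable features). `connectoscope` implements that full arc as one
config-driven, deterministic pipeline. Because such cohorts are usually
private, the package includes a generator that emulates two-group BOLD
data with known amplitude, coherence, and connectivity effects; every stage
is validated against that ground truth and against independent brute-force
oracles.

## The methods in brief

**Voxel metrics.** After trimming, detrending, ideal bandpass (0.01–0.08
Hz) and nuisance regression (6 motion parameters, WM/CSF components, global
mean), three maps are computed per subject: ALFF (mean square-root spectral
power in band), fALFF (its ratio to the full spectrum), and ReHo —
Kendall's coefficient of concordance

  W = 12 Σᵢ(Rᵢ − R̄)² / (m²(n³ − n))

between each voxel and its 26 neighbors. ALFF/fALFF smooth the 4D data
(6 mm FWHM) before computation; ReHo smooths the map afterwards. Maps are
z-standardized within the brain mask.

**Connectome and topology.** Mean parcel series → 90×90 Pearson matrix →
Fisher z = atanh(r) → binary graphs at sparsity S = 0.05…0.50 (step 0.01),
keeping the ⌊S·4005⌋ strongest |r| edges. Per threshold: modularity Q,
global/local efficiency, clustering Cp, characteristic path length Lp, and
the small-world indices γ = Cp/Cp_rand, λ = Lp/Lp_rand, σ = γ/λ against
degree-preserving rewired nulls, plus six nodal metrics; each curve is
summarized by its area under the curve (AUC) across the grid.

**Group statistics.** Voxel maps: GLM t on the group term with age, sex,
education and BMI as covariates; permutation-based cluster correction
(voxel p, cluster p, max-cluster-size null). Metric AUCs: two-sample
t-tests with Benjamini–Hochberg FDR within each metric family.

**Classification.** Feature blocks C (4005 Fisher-z edges), G (8 global
AUCs), N (540 nodal AUCs) and their combinations feed a multi-kernel SVM
(linear block kernels, trace-normalized, convex combination Σβₘ Kₘ) inside
nested leave-one-out cross-validation: t-test feature selection (p < 0.05)
and standardization are refit inside every training split; the inner loop
tunes (C, β). Consensus connections — edges selected in **every** outer
fold — form the stable discriminative signature.

## Worked example

Simulate a 52-subject cohort with a connectivity signature planted on ten
edges (Fisher-z +0.5 in the patient group), run it through the pipeline
stages, and classify. This is the package's standard validation scale and
takes a few minutes on one CPU:

```r
library(connectoscope)

spec <- ground_truth_spec(
  n_per_group = c(26, 26), grid_dims = c(10, 10, 10),
  n_volumes   = 240,
  edge_effect = data.frame(i = c(3, 7, 12, 20, 25, 31, 40, 47, 55, 60),
                           j = c(9, 15, 22, 28, 33, 42, 50, 58, 66, 70),
                           dz = 0.5),
  seed = 42)
cohort <- generate_cohort(spec)
cohort
#> synthetic_cohort: 52 runs (26 patients / 26 controls), 10x10x10 grid, 90 nodes

pp <- preprocess_run(cohort$runs[[1]], drop = 10)   # a patient's run
ts <- extract_roi_timeseries(pp$bandlimited, cohort$atlas)
cm <- fisher_z(pearson_matrix(ts))
round(cm$r[3, 9], 2)                 # planted edge; baseline r = 0.05
#> [1] 0.57

graphs <- graph_series(cm)           # 46 nested binary graphs
curves <- connectome_curves(graphs, n_rand = 10, seed = 1)
round(curves$auc_global, 3)
#>       Q E_global  E_local       Cp    gamma   lambda    sigma       Lp
#>   0.090    0.277    0.265    0.154    0.585    0.456    0.573    0.842
```

These are areas under the metric-versus-sparsity curve over the 0.45-wide
grid; `sigma`'s AUC of 0.573 corresponds to a grid-mean small-worldness
σ ≈ 1.3 (> 1: the block-correlated connectome is small-world, clustered
like a lattice but with near-random path lengths, as `gamma` ≈ 1.3 and
`lambda` ≈ 1.01 on the same scale show). The planted effect at edge (3, 9)
is visible directly in the subject's correlation: 0.57 against the 0.05
between-network baseline.

Classification over the full cohort (per-subject features from `cm` and
`curves` via `assemble_features()`):

```r
res <- nested_loocv(features, combo = "C", alpha = 0.05,
                    C_grid = c(0.1, 1), beta_step = 0.5, seed = 1)
res
#> classification_result [C]: accuracy 0.981, sensitivity 0.962,
#>   specificity 1.000, AUC 0.996; 111 consensus connections

head(res$consensus[, c("node_i", "node_j", "name_i", "name_j", "p")], 4)
#>   node_i node_j        name_i            name_j            p
#> 1      1     44  Precentral_L       Calcarine_R 2.081038e-02
#> 2      2     48  Precentral_R         Lingual_R 2.025211e-02
#> 3      2     86  Precentral_R    Temporal_Mid_R 2.171756e-02
#> 4      3      9 Frontal_Sup_L Frontal_Mid_Orb_L 1.257564e-18
```

All ten planted edges appear in the consensus with p-values around 10⁻¹⁸
(row 4 is the first of them); the remaining consensus edges are
sampling-noise edges that happen to pass the per-fold t-test in every
fold — with only 52 subjects their whole-sample p-values hover near the
0.05 selection threshold, which is exactly why the planted signature
stands out by orders of magnitude.

The whole pipeline runs as one call from a config:

```r
cfg <- validate_config("run.yaml")   # defaults: drop 10, band 0.01-0.08 Hz,
run_pipeline(cfg, "out/")            # FWHM 6 mm, S grid 0.05-0.50, ...
```

A thin CLI wrapper is installed at `inst/cli/connectoscope.R`
(`Rscript connectoscope.R run --config run.yaml --out DIR --seed 1`).

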