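---
title: "Methods: from BOLD time series to connectome classification"
author: "connectoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from BOLD time series to connectome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`connectoscope` implements a complete resting-state fMRI group-analysis
pipeline of the kind used in clinical case-control studies: voxelwise
activity metrics (ALFF, fALFF, ReHo), a 90-node functional connectome with
graph-theoretic topology, covariate-adjusted group statistics, and a
multi-kernel SVM classifier over connectome features. Because clinical BOLD
cohorts are rarely shareable, the package ships a synthetic-cohort generator
with planted, known effects; every stage of the pipeline is validated
against that ground truth.

This vignette records the models, the conventions chosen where the
literature admits more than one, and what the synthetic validation does and
does not establish.

## The synthetic cohort generator

The generator is a first-class module, not a fixture. It emulates a
two-group study (patients vs. controls) at the signal level:

1. **Node signals.** For each subject, white Gaussian noise per node is
   passed through an ideal spectral mask on the analysis band (default
   0.01–0.08 Hz, the canonical resting-state band), standardized, and mixed
   through the symmetric square root of a target correlation matrix. The
   empirical correlation therefore converges to the target as the series
   lengthens, and all spectral power lies inside the band by construction.
2. **Voxel rendering.** Each atlas parcel's voxels receive
   `amp * (sqrt(c) * s + noise_sd * sqrt(1-c) * eps)`: the shared node
   signal `s` plus independent voxel noise, so with `noise_sd = 1` the
   shared fraction of voxel variance equals the coherence `c`. Nuisance
   components (two slowly varying series standing in for white-matter and
   CSF signals) are mixed in with voxel-specific coefficients, and a
   smoothed-random-walk motion table is attached so motion QC has positive
   and negative cases to exercise.
3. **Planted group effects.** Group 1 may differ by per-node amplitude
   factors, per-node coherence deltas, and per-edge connectivity deltas
   applied on the Fisher-z scale of the target correlation and
   back-transformed (with an explicit error if a delta would push |r| to 1,
   and an eigenvalue-clipping repair if the perturbed matrix loses positive
   definiteness).
4. **Covariates.** Age ~ N(41, 13²) truncated to 18–60, sex ~ Bernoulli(½),
   education ~ N(12, 3²) years, BMI ~ N(24, 3²): the ranges of a
   middle-aged clinical cohort, so covariate adjustment runs under
   realistic conditioning.

Defaults are the study conditions the pipeline targets: 27 patients and 25
controls, TR = 2 s, 240 volumes (8 minutes), 90 nodes, baseline coherence
0.5, and a block-structured baseline correlation (r = 0.3 within a node's
network, 0.05 between; positive definite by construction). The atlas is a
farthest-point-seeded geodesic Voronoi parcellation of the grid interior:
contiguous, roughly equal parcels, deterministic for a fixed seed. No
published effect sizes were available to calibrate the planted effects, so
their defaults (zero) and the values used in validation were chosen for
testability, not fidelity to any particular disease.

**What the generator does not model:** hemodynamic-response convolution,
scanner artifacts, physiological (cardiac/respiratory) noise, spatial
normalization geometry, and between-subject variability in the *baseline*
correlation structure (subjects differ only through sampling noise and the
planted effects). Consequently, passing tests demonstrate that the
pipeline's machinery is correct and calibrated under its stated
assumptions — not that effect sizes of any particular magnitude are
detectable in real data, where inter-subject variance is substantially
larger.

## Preprocessing

Applied per voxel, in this order: drop the first 10 volumes
(signal-equilibration), linear detrend, ideal FFT-domain bandpass
(0.01–0.08 Hz), then nuisance regression (six motion parameters,
white-matter and CSF components when available, and the whole-brain mean).
Motion QC excludes a run when any translation exceeds 3 mm **or** any
rotation exceeds 3° — "exceeds" strictly, so maxima exactly at the limit
are retained — and the decision is reported, never silently applied.

Two conventions deserve note:

* **Ideal mask, not IIR.** The bandpass zeroes DFT bins outside the band.
  This matches the convention of the standard resting-state toolchains, is
  exactly testable (a bin-centered tone passes untouched), and is
  idempotent.
* **Band-filtered regressors for the band-limited branch.** Regressing
  broadband nuisance series out of band-limited data reintroduces
  out-of-band power into the residual. The band-limited branch (feeding
  ReHo and connectivity) therefore uses band-filtered copies of the
  regressors; the broadband branch (feeding ALFF/fALFF, whose full-spectrum
  denominator requires broadband input) uses them as is. ALFF on
  band-limited data would make fALFF degenerate to ≈1, which is why the
  two branches exist.

## Voxel metrics

* **ALFF** is the mean of the square-root power (one-sided DFT amplitude
  spectrum, DC excluded) over the in-band bins; **fALFF** divides the
  in-band sum by the full-spectrum sum. Both are computed on data smoothed
  (6 mm FWHM Gaussian) *before* the spectral step.
* **ReHo** is Kendall's coefficient of concordance
  `W = 12 Σ(R_i − R̄)² / (m²(n³−n))` between each voxel and its 26
  neighbors (27-voxel cube; 7/19 configurable), midranks for ties,
  boundary voxels using the neighbors available inside the mask. The map
  is smoothed *after* computation — the reverse order from ALFF,
  deliberately.
* **Smoothing** is separable Gaussian with
  `σ = FWHM/(voxel·2√(2 ln 2))`, truncated at 4σ and renormalized over the
  available (in-mask) support, so constant fields are exact fixed points
  and mask boundaries are not attenuated.
* **Standardization** of the three maps for group analysis is within-mask
  (x−μ)/σ. The amplitude metrics are unbounded, so a correlation-style
  atanh transform is undefined for them; the within-mask z-score is the
  convention of the standard toolchain and is what "z-maps" means here.

## Connectome construction

Mean parcel time series → 90×90 Pearson matrix → Fisher z (|r| clipped at
1−10⁻⁷ so duplicated signals stay finite) → binary graphs across the
sparsity grid S = 0.05, 0.06, …, 0.50 (46 thresholds). Sparsity S keeps
the `floor(S·4005)` edges of largest **absolute** correlation — the
signed-vs-absolute choice is not settled in the field; absolute ranking
retains strong anticorrelations, and ties are broken lexicographically by
node pair so the series is deterministic and nested. Node-to-network
labels (7 cortical resting-state networks plus Subcortical) come from a
packaged, curated lookup table; it is an approximate static assignment,
not a spatial-overlap computation.

## Graph topology

Eight global metrics (modularity Q, global efficiency, local efficiency,
clustering coefficient Cp, γ, λ, σ, characteristic path length Lp) and six
nodal metrics (betweenness, degree, nodal Cp, nodal efficiency, nodal
local efficiency, nodal shortest path) are computed per threshold, then
summarized as the trapezoidal area under the metric-versus-sparsity curve
(AUC), the threshold-free quantity used for group tests and classifier
features.

Conventions for sparse, possibly disconnected graphs (the low-S end of the
grid routinely disconnects): efficiencies use 1/∞ = 0; Lp and nodal
shortest path average over reachable pairs only; nodes of degree < 2
contribute 0 to clustering and local efficiency. Betweenness is
unnormalized (raw fractional pair counts). Modularity is Newman modularity
of the best partition found by deterministic greedy agglomeration
(igraph's CNM implementation) — reproducibility was preferred over
stochastic refinement, since the optimization algorithm is a free choice
here.

γ and λ normalize Cp and Lp by their means over degree-preserving
Maslov–Sneppen rewired null networks (default 100 nulls per threshold,
10×edge-count swap attempts), and σ = γ/λ identically. Distances are
computed by simultaneous breadth-first search via boolean matrix products,
which is substantially faster than per-node traversals at this density and
matches an independent Floyd–Warshall oracle exactly in the test suite.

## Group statistics

Voxel maps are compared by the GLM `value ~ intercept + group + age + sex
+ education + BMI`; the reported statistic is the t on the group
coefficient. Correction is permutation-based: voxel-level two-tailed
threshold (default p < 0.01), 6-connectivity clusters, and a max-cluster-
size null over group-label permutations (covariates stay attached to their
subjects); a cluster survives when its size exceeds the 1−cluster_p
quantile of that null. Covariates that are constant or exactly confounded
with group in a given cohort are dropped with a log message rather than
letting the design go singular — a situation that small cohorts do
produce. Network-metric AUCs are compared by two-sample Student's t-tests
(covariate adjustment available but off by default, matching the plain
two-sample description of that analysis), with Benjamini–Hochberg FDR
applied within each metric family: the 8 global metrics form one family
and each nodal metric's 90 node tests form their own.

## Classification

Feature blocks per subject: **C** — 4005 Fisher-z edge weights (upper
triangle, lexicographic order), **G** — 8 global AUCs, **N** — 540 nodal
AUCs (metric-major). Any of the seven combinations C, G, N, C+G, C+N,
G+N, C+G+N runs through the same engine.

Nested leave-one-out cross-validation: the outer loop holds out one
subject; the inner loop (leave-one-out on the remainder) selects the SVM
cost C and the kernel weights β over a simplex lattice. **Feature
selection (two-sample t-test at p < 0.05 on C and N; G always passes
whole) and feature standardization are refit inside every training split —
per inner fold during tuning, per outer fold for the final model.**
Refitting selection inside the inner folds matters: if the outer fold's
selection is reused, the inner accuracy is selection-biased toward
saturation, every configuration ties, and the smaller-C tie-break then
systematically returns underfit models. Ties are broken toward smaller C
(stronger regularization), then lexicographically smaller β.

Each block's kernel is the linear Gram of train-standardized features,
trace-normalized to the training-set size. Because all block kernels are
linear, the combined kernel Σβ·K equals the Gram of the concatenated
√β-scaled features, so the cross-validation engine fits an equivalent
linear SVM (LIBSVM via e1071) in feature space — identical solutions,
roughly 4× faster than solving in kernel space; the kernel-space
multi-kernel trainer (kernlab) is retained as the exported operation, and
a test asserts the two routes agree. Kernel type, C grid (2⁻⁵…2⁵ powers of
two) and β lattice step (0.1) are not reported in the source literature of
this design; the defaults are standard MKL practice and configurable.

Consensus connections are the intersection of the outer folds' selected C
features — the edges selected in *every* validation — reported with node
names, network labels, and whole-sample p-values. Performance is
summarized as accuracy, sensitivity (patients positive), specificity, an
ROC sweep over decision values, and the rank-statistic (Mann–Whitney) area.

## Pipeline, determinism, and provenance

`validate_config()` merges a YAML/JSON/list over defaults (every default
matching a stated protocol value where one exists: drop 10, band
0.01–0.08 Hz, FWHM 6 mm, sparsity 0.05–0.50 step 0.01, α 0.05,
voxel/cluster p 0.01) and reports all violations together.
`run_pipeline()` executes simulate → preprocess → voxel metrics → stats →
connectome → graph → metric tests → classify, writing NIfTI/TSV/JSON
outputs and a manifest with MD5 checksums. Every random stage derives its
seed from the single config seed, so identical configs reproduce
byte-identical manifests; wall-clock timings go to a separate log so they
cannot perturb the manifest. The exported functions are the primary
interface; a thin command-line wrapper over them ships in `inst/cli/`.

## Validation problem sizes

The test suite validates exactness against independent oracles
(Floyd–Warshall distances, exhaustive shortest-path enumeration for
betweenness, direct-sum DFT, rank-sum Kendall W, step-up FDR, normal-
equation GLM) and statistical calibration by simulation. Sizes were chosen
so the whole suite stays comfortably re-runnable on one CPU: graph-metric
oracle equivalence is exhaustive over all labeled connected graphs on ≤ 5
nodes plus hundreds of random 6-node graphs; calibration uses ≥ 200 null
cohorts of 26+26 subjects on reduced grids (4-node, ~60-volume runs) and
100 cohorts × 500 permutations for the cluster-level familywise error;
recovery uses 10 cohorts of 26+26 with Δz = 0.5 planted on 10 edges at the
default series length, with connection features taken from the generator's
node-level signals through the package's own correlation/Fisher-z path
(voxel rendering, which only attenuates those features mildly, is
exercised separately by the end-to-end run); end-to-end determinism runs
the full pipeline twice
on a 12×12×12, 52-subject cohort with reduced volume count, null count and
permutation count. Stochastic calibration checks use pre-registered 99%
intervals around the nominal rates.

## Known limitations

* The generator's subjects share one baseline correlation matrix per
  group; real cohorts carry subject-level connectome variability, so
  classifier accuracies on synthetic cohorts overstate what identical
  effect sizes would yield in vivo.
* Gaussian-random-field cluster correction and surface-based metrics are
  not implemented; permutation correction is the only cluster-level route.
* Weighted-graph and dynamic (sliding-window) connectivity are out of
  scope; graphs are binary by construction of the sparsity threshold.
* The node→network lookup is a static approximation; studies needing exact
  overlap-based assignment should replace the packaged table via
  `load_network_labels(path)`.
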