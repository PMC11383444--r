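---
title: "Masked graph networks for multimodal connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked graph networks for multimodal connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the feature
definitions, the model and objective, the synthetic cohort the tests rely
on, and the numerical and design decisions taken where the methodology
left genuine choices open. It states no empirical result that the test
suite or `scripts/acceptance.R` do not themselves compute.

## Problem setting

Multimodal neuroimaging gives three complementary views of each subject's
brain on a common parcellation of `Q` regions: functional connectivity
(FC) from resting-state BOLD, structural connectivity (SC) from
tractography streamline counts, and regional anatomical statistics (AS)
from surface morphometry. The package predicts a cognitive score (or an
extreme-group membership) from all three at once, through a graph neural
network whose central parameter — a population-level symmetric edge mask
— is the interpretation: after training, large mask entries name the
connections the prediction relied on.

## Feature derivation

**FC.** Pearson correlation between every pair of ROI time series
(diagonal exactly 1), then min-max scaled to [0, 1] within subject.

**SC.** Raw streamline counts are divided by the square root of the
product of the two regions' gray-matter volumes, removing the tendency of
larger regions to accumulate more streamlines, then min-max scaled over
the off-diagonal entries. The diagonal stays zero and volumes must be
strictly positive (they sit under a square root in a denominator).

**Intrinsic neural timescale (INT).** Per region, with repetition time
`TR` (seconds) and lag-`k` sample autocorrelation
`r(k) = sum_t (y_t - ȳ)(y_{t-k} - ȳ) / sum_t (y_t - ȳ)²`
(one shared mean, the full sum of squares in the denominator — not a
per-lag re-centred variant), the estimator is `TR * sum_{k=1}^{N} r(k)`
where `N` is the last lag before `r` first turns negative: the area under
the initial positive phase of the autocorrelation function, a duration in
seconds. Conventions at the boundaries: if `r(1) < 0` the timescale is 0;
if `r` never turns negative the sum runs to the largest computable lag,
`T - 2`. The estimator is applied directly to ROI-mean time series; when
the upstream data are voxel-wise, the voxel estimate averaged within
region has the identical form, so this is a deliberate, documented
approximation that avoids any voxel-level input.

**Structure–function coupling.** Per region, the Spearman rank
correlation between its SC row and its FC row, restricted to the partners
it is structurally connected to (SC > 0) and excluding the diagonal. The
restriction to the structural support follows the standard
coupling convention in the connectomics literature; regions with fewer
than 3 structural partners get coupling 0 and a flag (the value is
undefined there, and 0 is the neutral point of the scale).

**AS table.** Nine morphology columns (vertex count, surface area,
gray-matter volume, mean/SD cortical thickness, mean and Gaussian
curvature, intrinsic curvature index, folding index) plus INT and
coupling, in that fixed order (`d_c = 11`). Each column is
log-transformed (variance stabilization) and min-max scaled. `log1p`
after a shift that makes the argument nonnegative is the default because
morphology counts can contain zeros and coupling is bounded negative;
plain `log` is available for strictly positive tables.

**Scaling scope.** All min-max scaling is computed *within subject* (per
matrix, per AS column). Nothing else in the pipeline then needs a second
pass over the cohort, and no subject's features depend on who else was
sampled. Cohort-level scaling would preserve between-subject mean offsets
that per-subject scaling removes; the synthetic generator therefore
encodes its anatomical signal as a within-subject spatial contrast (see
below), which survives per-subject scaling.

## Graph construction

The graph is built from FC for multimodal runs and from SC for SC-only
runs. Each node keeps its `k = 30` strongest connections above the
threshold 0.001; when fewer exist, it keeps what it has. Symmetrization
is by union — an edge survives if either endpoint selected it — which
keeps sparse SC graphs connected and means node degree may exceed `k`
(an intersection rule is available). The adjacency carries the scaled
connectivity values as weights; a binary variant sits behind a flag. Node
input features are the concatenated FC and SC profile rows (`d0 = 2Q`
multimodal, `Q` single-modality); the anatomical table is *not* part of
the input layer but fused after the first graph layer.

## Model

The mask is `M = sigmoid(V + Vᵀ)` with `V` a free `Q × Q` matrix:
symmetric by construction, entries strictly in (0, 1), shared across
subjects and across both layers. One masked graph-convolution layer
computes `H' = φ((M + I) ⊙ S · H · Θ)` where `S = D̃^{-1/2} Ã D̃^{-1/2}`,
`Ã = A + I`. The added identity guarantees an identity mapping at
`M = 0` (the filter cannot degenerate to the null matrix), and because
the mask enters through a Hadamard product with `S`, it only modulates
existing edges and self-loops — it cannot create connections. The mask's
diagonal is trained but redundant with the `+ I` term, and interpretation
ignores it.

Layer 1 embeds the connectivity profiles; its output is concatenated
node-wise with the scaled AS table; layer 2 (same mask) embeds the fused
representation; mean pooling over nodes and a one-hidden-layer dense
readout produce the prediction (one or more regression targets, or two
class logits).

Choices the architecture description left open, fixed here:

- **Pooling: mean.** Preserves permutation consistency and keeps all
  edge-level saliency in the mask rather than in the pooling. Sum and max
  are available behind a flag.
- **Activations: ReLU** on both graph layers and the readout hidden
  layer, identity on the output.
- **Widths: d1 = d2 = 64, readout hidden 32** — config-exposed defaults
  at the scale of the cohorts the package targets.

The key structural correctness property — predictions invariant under a
joint permutation of the node order in the adjacency, the feature rows,
the AS rows and both index dimensions of `V` — is asserted in the test
suite over random permutations, alongside a dense-matrix oracle for the
layer itself and full finite-difference checks of the analytic gradients.

## Objective

`L = L_e + α · L_manifold + L_mask` with

- `L_e`: MSE averaged over targets and subjects, or cross-entropy from
  logits;
- `L_manifold = ½ Σ_q Σ_{j∈N(q)} ‖h_q − h_j‖² = tr(Hᵀ L H)`: the two
  forms are equal exactly when `L` is the *unnormalized* Laplacian of the
  *binary* support of the subject's adjacency, which is the reading
  implemented (the definitional double sum has unit weights); the
  equality is itself a test.
- `L_mask = λ1‖M‖₁ + λ2‖M‖²_F + λ3‖M Mᵀ − I‖_F`: sparsity plus a soft
  push toward orthonormal, basis-like rows. A *hard* orthonormality
  constraint (unit-norm, zero-mean rows) is not implementable for a
  matrix with entries in (0, 1) — sigmoid-range rows cannot have zero
  mean — so only the soft penalty is enforced.

Batch reduction: `L_e` and `L_manifold` are means over the subjects of
the batch; `L_mask` is computed once per optimization step, because the
mask is population-level, not per-subject.

## Training protocol

Adam (the standard adaptive first-order choice; the protocol names only
the schedule and the L2 term) with initial learning rate 0.005, batch
size 32, at most 50 epochs, weight decay 1e-6 on all parameters, and a
reduce-on-plateau schedule: when the validation objective fails to
improve for 10 epochs the learning rate is halved (floor 1e-5). The
best-validation parameters are returned. Splits are 70/10/20
train/validation/test, stratified by label for classification so the
extreme-group balance survives splitting. A manifold monitor watches the
batch-mean `L_manifold`; if it falls below a configured floor (default
1e-4) — the signature of embedding collapse/oversmoothing — `α` is
halved and the event logged. Halving is the mildest corrective action
that provably stops the pressure toward collapse; the monitor's
corrective action was otherwise unspecified.

Repeated evaluation (`bootstrap_runs`) re-draws the splits and re-seeds
initialization and training `n` times (default 10) and reports mean ± sd
per metric, with a Welch t-test utility for model comparisons. Re-drawn
splits (rather than resampling subjects with replacement) keep every
evaluation on genuinely held-out subjects.

Mask-penalty weights default to `λ1 = λ2 = 1e-3`, `λ3 = 1e-2`,
`α = 1e-4`. They were fixed once by a small validation sweep on synthetic
cohorts (the protocol prescribes hyperparameter search), balancing
held-out error against the sharpness of the mask's edge ranking; all four
are config-exposed.

## The synthetic cohort generator

The generator emulates the statistical structure the features assume,
with known ground truth:

1. ROIs belong to `n_blocks` communities; the BOLD innovation correlation
   is `ρ_in = 0.5` within blocks, `ρ_out = 0.1` between, plus symmetric
   per-subject jitter (sd 0.05). If the jitter breaks positive
   definiteness the matrix is projected back to the nearest valid
   correlation matrix.
2. Each ROI has an AR(1) coefficient spread over [0, 0.6], so intrinsic
   timescales genuinely vary by region; the time series are the AR
   recursion driven by correlated innovations (200 burn-in steps), and
   the implied stationary correlation is stored as ground truth —
   sample FC converges to it as `T` grows (tested).
3. SC counts are Poisson with block-modulated rates (within 30, between
   0.5, times a subject-level gamma factor), symmetrized, zero diagonal —
   sparse between blocks, dense within, echoing the FC communities.
4. Volumes and morphology columns are log-normal with fixed ROI profiles.
   Every morphology column carries a subject-specific *spatial contrast*
   (a subject-varying shift on the first quarter of ROIs); this is what
   lets a per-subject min-max-scaled column still differ between
   subjects.
5. The target is
   `y = β_edge · z(Σ_{(i,j)∈E*} FC_ij · SC_ij) + β_as · z(Σ_{c∈S*} mean_q AS_qc) + ε`,
   where `E*` is a planted 5% of the within-block pairs, `S*` a planted
   subset of 3 morphology columns, and both components are computed from
   the *scaled* features (the quantities the model can actually see) and
   standardized across the cohort so `β_edge = β_as = 1` are effect sizes
   in SD units against noise `ε ~ N(0, 1)`. Labels are a median split of
   `y`, or extreme-group quantiles with the middle left unlabelled.

Defaults (n = 300 subjects, Q = 40 ROIs, 4 blocks, T = 400 time points,
TR = 0.72 s) keep a full train/interpret cycle under a minute on one CPU
while preserving the statistical regime: a planted minority of predictive
edges inside a realistic community structure, heterogeneous timescales,
and anatomical signal that must survive scaling. The unit tests use
smaller cohorts (n = 60, Q = 20, T = 120); the end-to-end recovery tests
and the acceptance script use the full defaults.

What the generator does **not** emulate: hemodynamic forward models,
voxel-level structure, scanner/site effects, motion artefacts, realistic
streamline-count marginals, or correlations between morphology columns.
Passing recovery tests therefore demonstrates that the estimator and its
interpretation machinery work when the generative assumptions hold — not
that they are robust to the full messiness of acquired data.

## Numerical conventions and degenerate inputs

- Min-max of a constant array is defined as all zeros (avoids 0/0, stays
  in range).
- Constant time-series columns are errors for FC and INT (zero
  denominators), named by ROI.
- An all-zero SC matrix is an error for coupling; regions with < 3
  structural partners get coupling 0, flagged.
- The visualization threshold compares mask entries directly on their
  (0, 1) scale; a variant applying a second sigmoid before comparing
  (meaningful thresholds then live in (0.5, 0.731)) is available behind a
  flag, since both conventions appear in the literature. Thresholding is
  strict (`>`), the diagonal is excluded, and the exported edge list
  sorts by weight with lexicographic tie-breaks. Because the absolute
  mask scale depends on the sparsity penalties, a quantile of the learned
  mask distribution is often the practical threshold choice.
- Gradients for classification attribution are taken on the selected
  class logit (standard practice for gradient-times-activation maps);
  attribution vectors are softmax-normalized per subject and averaged
  across subjects afterwards.
- All randomness flows from the single seed in `run_config` /
  `synthetic_spec`, with stage-specific derived seeds, so every fit and
  every cohort is bit-reproducible.

## Limitations

The model is transductive in its mask: `M` is `Q × Q` for one fixed
parcellation, and a mask learned on one atlas does not transfer to
another. Mask identifiability is relative — penalties shift the whole
mask's scale, so interpretation should use rankings or quantile
thresholds, not absolute values. The manifold term uses the binary graph
support, not the learned mask, so it regularizes embeddings over the
fixed topology. Training is full-batch-gradient per subject graph in
plain R; it is comfortable at atlas scales (Q ≤ a few hundred) but not
engineered for voxel-scale graphs.
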