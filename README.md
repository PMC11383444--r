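# maskgnn

Interpretable multimodal brain-network modelling in R: functional
connectivity (FC), structural connectivity (SC) and regional anatomical
statistics (AS) are derived on a shared cortical parcellation, fused in a
masked graph convolutional network, and trained against cognitive scores.
The model jointly learns a population-level **edge-importance mask**, so
the fitted object explains *which connections* drive the prediction
(thresholded mask, network-level aggregates) and *which regional features*
matter (Grad-RAM/Grad-CAM gradient attribution).

The package is aimed at connectomics researchers who have ROI-level
derivatives (BOLD time series, streamline counts, morphometry tables) and
want a phenotype-prediction model whose parameters are themselves the
interpretation. Because cohort data of this kind are usually access
restricted, the package ships a synthetic multimodal cohort generator with
planted ground truth (predictive edges, informative anatomical columns),
so the full pipeline — features, training, interpretation — is testable
end to end without any data download.

## The model

All subjects share a parcellation with `Q` regions (nodes). Per subject:

- **FC**: Pearson correlation between ROI time series, min-max scaled.
- **SC**: streamline counts normalized by regional gray-matter volumes,
  `SC(i,j) / sqrt(V_GM(i) * V_GM(j))`, then min-max scaled.
- **INT** (intrinsic neural timescale): `TR * sum_{k=1}^{N} r(k)` — the
  area under the initial positive phase of the signal's autocorrelation
  function, where `N` is the last lag before `r` first turns negative.
- **Structure–function coupling**: per region, the Spearman correlation
  between its SC profile and its FC profile over its structural
  connections.
- **AS**: nine surface-morphology measures plus INT and coupling
  (`d_c = 11` columns), log-transformed and min-max scaled.

The graph keeps each node's top-`k` supra-threshold connections
(`k = 30`, threshold `0.001`, union-symmetrized). Node features are the
concatenated FC/SC connectivity profiles. The network is

```
M  = sigmoid(V + V')                    # learned symmetric edge mask
H1 = relu((M + I) ⊙ S · H0 · Θ1)        # S = D^-1/2 (A + I) D^-1/2
H2 = relu((M + I) ⊙ S · [H1 ‖ C] · Θ2)  # C = anatomical table, fused node-wise
ŷ  = readout(mean-pool(H2))
```

with one free matrix `V` shared by both layers and all subjects, trained
jointly with the weights under the composite objective

```
L = L_e(ŷ, y) + α · tr(H2' L H2)
    + λ1‖M‖₁ + λ2‖M‖²_F + λ3‖M M' − I‖_F
```

(prediction error, manifold smoothness of the embeddings over the graph
Laplacian, and mask sparsity/orthonormality). Optimization is Adam
(initial learning rate 0.005, batch 32, ≤ 50 epochs) with a
reduce-on-plateau schedule (patience 10), weight decay 1e-6, and a
manifold monitor that halves `α` if embeddings oversmooth.

## Worked example

```r
library(maskgnn)

spec   <- synthetic_spec(n_subjects = 120, q = 30, n_blocks = 3,
                         t_len = 200, seed = 7)
cohort <- featurize_cohort(generate_cohort(spec))
cohort
#> <maskgnn_cohort> 120 subjects, Q = 30 ROIs, 7 planted edges, 3 informative AS columns

fit <- maskgnn(cohort, run_config(q = 30, seed = 7))
fit
#> Masked graph neural network fit
#>   task: regression   modalities: FC+SC+AS   Q = 30 ROIs
#>   epochs run: 50   final lr: 0.005
#>   test RMSE 1.6586   test MAE 1.3962
```

The held-out RMSE (1.66) beats the best constant predictor (`sd(y)` =
1.78) on this small, noisy cohort. The learned mask ranks the planted
predictive edges far above chance:

```r
mask_edge_auc(coef(fit), cohort$truth$planted_edges)
#> [1] 0.903

m  <- coef(fit)                                  # Q x Q mask in (0, 1)
tm <- threshold_mask(m, quantile(m[upper.tri(m)], 0.95))
tm
#> <thresholded_mask> t = 0.255601, 22 retained edges (Q = 30)
head(tm$edges, 3)
#>   i j    weight
#> 1 1 7 0.2728214
#> 2 2 7 0.2714147
#> 3 2 5 0.2675319
```

Three of the seven planted edges (2–5, 2–7, 4–7) appear directly among the
top retained pairs, and all retained edges are intra-community, matching
the planted block structure. The absolute mask scale depends on the
sparsity penalties, so the visualization threshold is best chosen relative
to the mask distribution (here its 95th percentile). Gradient attribution
of the fused anatomical block gives a probability vector over the 11 AS
columns (larger = more influential for the prediction):

```r
round(sort(grad_attribution(fit, cohort), decreasing = TRUE), 4)[1:4]
#> IntrinsicCurvatureIndex           MeanCurvature       GaussianCurvature
#>                  0.0936                  0.0933                  0.0909
#>            ThicknessStd
#>                  0.0907
```

A command-line front end wrapping the same functions ships in
`inst/cli/maskgnn.R` (`simulate`, `featurize`, `train`, `evaluate`,
`interpret`, `ablate`).

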