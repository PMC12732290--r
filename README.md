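# dermselect

Quantum-behaved particle swarm feature selection for multi-class
skin-lesion classification.

Dermoscopic benchmarks such as HAM10000 (7 lesion classes), ISIC 2019
(8 classes) and MSLD v2.0 (6 classes) are strongly imbalanced, and deep
feature extractors emit many more features than a downstream classifier
needs. `dermselect` implements the full method stack around that problem:

* **QBPSO core** — a quantum-behaved particle swarm optimizer. Each
  particle j collapses toward a local attractor
  `p_j = ξ ⊙ Lbest_j + (1 − ξ) ⊙ Gbest`, `ξ ~ U(0,1)`, and its next
  position is sampled from the potential-well law
  `x'_{j,d} = p_{j,d} ± β · |mbest_d − x_{j,d}| · ln(1/u_d)`,
  where `mbest` is the mean of all personal bests and the
  contraction–expansion coefficient anneals as
  `β = 0.9 (1 − t/T) + 0.1`. A textbook inertia-weight PSO
  (`spso_optimize()`) is included as a comparison baseline.
* **Wrapper feature selection** — continuous positions in `[−1, 1]^D` are
  thresholded to binary masks S; a mask is scored by
  `−(L + λ |S| / D)` where L is the label-smoothed cross-entropy of a
  softmax-regression classifier trained on the masked columns of an
  internal stratified split (λ = 0.01 by default). An exhaustive
  `2^D`-mask oracle is provided for small D.
* **MBConv blocks** — the computational blocks of a compact
  EfficientNet-style extractor: 1×1 expansion, depthwise convolution,
  squeeze-and-excitation gating `sigmoid(W2 relu(W1 ℘))`, linear
  projection with residual, swish activations, single-head self-attention
  over spatial tokens, compound scaling `(α^ϑ, β^ϑ, γ^ϑ)` with
  `α β² γ² ≈ 2`, and MAC accounting.
* **Data preparation** — SMOTE balance planning and generation
  (`x + δ (x_nn − x)`, δ ~ U(0,1), k = 5 Euclidean neighbors), stratified
  70/30 splitting, and synthetic fixture generators (lesion-like images
  and feature tables with planted informative columns) so everything is
  testable without downloads.
* **Metrics** — per-class precision/recall/FNR/F1/specificity/FPR,
  Matthews correlation (binary and macro one-vs-rest), bias-corrected
  excess kurtosis, and Monte-Carlo run aggregation with ANOVA-F and
  two-sample-t comparisons.

## Worked example

```r
library(dermselect)

# a 200-sample table: 3 classes, 12 features, 3 planted informative
fm <- generate_synthetic_features(
  synth_config(n = 200, n_features = 12, n_informative = 3,
               effect_size = 3, seed = 1))

sel <- run_selection(fm, fitness_spec(lambda = 0.01, seed = 1),
                     qbpso_config(dimension = 12, num_particles = 30,
                                  max_iter = 100, maximize = TRUE,
                                  seed = 1))
sel
#> QBPSO feature selection
#>   selected: 5 of 12 features
#>   score: -0.3781242
#>   held-out accuracy: 0.9516129
sel$selected_indices
#> [1] 1 2 3 4 6
```

The swarm keeps all three planted informative columns (1–3), discards
most noise columns, and the selected subset classifies the untouched
30 % held-out partition at 95 % accuracy. The score is the negated
objective `L + λ|S|/D`, so less negative is better; on problems this
size it equals the optimum of an exhaustive search over all 4096 masks.

The same run is available from a shell:

```sh
inst/cli/dermselect synth  --mode features --out feat.tsv --n 200 \
    --features 12 --informative 3 --seed 1
inst/cli/dermselect select --features feat.tsv --out sel/ --seed 1
```

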