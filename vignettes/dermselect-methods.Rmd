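---
title: "Quantum-behaved swarm feature selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-behaved swarm feature selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermselect)
```

## The problem

Multi-class skin-lesion classification pipelines typically couple a deep
feature extractor with a conventional classifier head. Two practical
problems dominate: the public dermoscopic benchmarks are heavily
imbalanced (one majority class can outnumber a minority class by a factor
of fifty), and the extracted feature vectors carry many uninformative
dimensions that slow training and hurt generalization. `dermselect`
addresses both with SMOTE-based balancing and wrapper feature selection
driven by a quantum-behaved particle swarm optimizer (QBPSO), together
with the mobile-inverted-bottleneck (MBConv) computational blocks of a
compact EfficientNet-style extractor so the entire chain can be exercised
and tested on synthetic data.

## The optimizer

QBPSO replaces the velocity/position recursion of standard PSO with a
probabilistic update derived from a quantum potential-well model. With
personal bests $L_j$, global best $G$, and mean-best
$m = \frac{1}{M}\sum_j L_j$, each particle collapses toward a local
attractor

$$p_j = \xi \odot L_j + (1-\xi)\odot G, \qquad \xi \sim U(0,1)^D,$$

and its next position is sampled per dimension as

$$x_{j,d}' = p_{j,d} \pm \beta\,\lvert m_d - x_{j,d}\rvert \,
  \ln(1/u_d), \qquad u_d \sim U(0,1],$$

with the $\pm$ branch taken with probability one half per dimension. The
single control parameter is the contraction–expansion coefficient
$\beta$.

**β schedule.** Two parameterizations circulate for this optimizer: a
linear anneal $\beta = 0.9\,(1 - t/T) + 0.1$ and a constant
$\psi = 0.8$. The annealed schedule is the operationally complete
description (it specifies β at every iteration), so it is the default;
the constant mode remains available via `beta_mode = "constant"`. An
*attraction coefficient* of 0.85 is sometimes quoted alongside these
settings but corresponds to no symbol in the update equations; it is kept
as an inert, documented configuration field.

**Numerical choices.** Positions are clipped to the search box (default
$[-1,1]^D$, the scaling under which the binary mapping below is
symmetric). Non-finite objective values are treated as worst-possible
scores, which keeps the loop total without crashing a long run. The
bookkeeping order per iteration is: score all particles, update
personal/global bests, refresh the mean-best once, then move every
particle — interleaving the mean-best refresh with per-particle updates
would let non-improving iterations skip it. Termination by the
`function_tolerance` ($10^{-10}$ by default) is only meaningful against a
reference optimum, so it activates solely when the caller declares a
known zero optimum (`known_optimum_zero = TRUE`, true for the test
functions and for loss-type objectives bounded below by zero); otherwise
the swarm runs to `max_iter`. Iteration presets follow the two quoted
regimes: 350 for feature selection, 1000 for continuous optimization.

## The selection objective

A candidate subset is a bit vector $S \in \{0,1\}^D$. Continuous
positions map to bits deterministically: $S_d = 1$ iff $x_d \ge 0$
(equivalently $\mathrm{sigmoid}(x_d) \ge 0.5$; ties map to 1). The
deterministic rule makes the fitness a pure function of the mask, which
is what lets an exhaustive $2^D$ oracle certify the swarm's optimum on
small problems; the stochastic transfer rule of binary PSO is available
as an option.

A mask is scored by

$$\mathrm{score}(S) = -\bigl(L(S) + \lambda\,\lvert S\rvert / D\bigr),$$

maximized by the swarm. $L(S)$ is the label-smoothed cross-entropy of a
multinomial softmax-regression classifier trained on the masked columns
of an internal stratified 70/30 split of the outer training partition and
evaluated on the internal validation part:

$$L = -\frac{1}{N}\sum_{i=1}^{N}\sum_{c=1}^{C} y_{ic}\,\log \hat y_{ic},
\qquad y_{ic} = \begin{cases} 1-\varepsilon+\varepsilon/C & c = c_i\\
\varepsilon/C & \text{otherwise.}\end{cases}$$

Choices worth stating explicitly:

* **Penalty form.** Normalizing the cardinality by $D$ makes
  $\lambda = 0.01$ mean the same thing on a 12-feature toy table and a
  64-feature extractor output. The mean (rather than sum) over samples in
  $L$ likewise makes $\lambda$ batch-size independent.
* **Inner classifier.** Softmax regression trained by full-batch gradient
  descent is used because the label-smoothed cross-entropy is exactly its
  training loss; it is deterministic (zero initialization), fast enough
  for thousands of evaluations per swarm run (the fitting loop is
  compiled C++), and standardizes columns by training statistics for
  conditioning. Defaults: $\varepsilon = 0.1$, learning rate 0.5,
  150 epochs — at these settings the classifier reaches the
  nearest-class-mean oracle on the planted synthetic tables, so more
  epochs buy nothing.
* **Empty masks** receive a $-\infty$ sentinel rather than a repaired
  random bit; repairs would hide optimizer behavior from the tests.
* **Fitness is frozen per run.** The internal split is drawn once per
  `run_selection()` call, not once per evaluation, so the objective is a
  fixed deterministic function during the search.
* **Evaluation protocol.** The outer data are split 70/30 (stratified);
  the fitness only ever sees the training partition. Reported metrics
  come from retraining on the full outer training partition with the best
  mask and scoring the untouched outer test partition.

## The extractor blocks

One MBConv block computes, for input $X \in \mathbb{R}^{H\times W\times
C_{in}}$:
expansion $Z = g(X * W_{exp})$ to $t\,C_{in}$ channels ($t = 6$ by
default, $g$ the swish $t\,\sigma(t)$); depthwise convolution
$Z_{dw} = g(Z \odot W_{dw})$ with one $k\times k$ filter per channel,
"same" padding, channels-last; squeeze-and-excitation
$\wp_c = \mathrm{mean}_{i,j} Z_{dw}(i,j,c)$,
$\mathrm{CA} = \sigma(W_2\,\mathrm{relu}(W_1 \wp))$,
output $\mathrm{CA}_c \cdot Z_{dw}(i,j,c)$; linear $1\times1$ projection
to $C_{out}$; residual added iff stride is 1 and $C_{in} = C_{out}$.

Two block-level conventions were genuinely open:

* **Gate operator order.** One printed form of the squeeze-excitation
  gate applies ReLU outside and sigmoid inside, which yields an unbounded
  gate and breaks the recalibration semantics (gates in $(0,1)$ scaling
  each channel). The standard order
  $\sigma(W_2\,\mathrm{relu}(W_1\wp))$ is implemented as the default and
  the literal reversed order is retained behind `literal_gate = TRUE`.
  The squeeze width is $\lceil 0.25\,C_{in} \rceil$ (the usual
  squeeze-ratio convention; no width is quoted anywhere).
* **Attention placement.** Self-attention over a single pooled vector is
  degenerate (a 1×1 attention matrix is the identity), so the refinement
  runs over the $H\cdot W$ spatial tokens immediately *before* global
  average pooling: single-head scaled dot-product,
  $\mathrm{softmax}(QK^\top/\sqrt{d_k})\,V$, rows summing to one.

Compound scaling multiplies depth, width and resolution by
$(\alpha^\vartheta, \beta^\vartheta, \gamma^\vartheta)$ under
$\alpha\beta^2\gamma^2 \approx 2$ (checked against $[1.8, 2.2]$), and
`count_flops()` verifies the implied approximate MAC doubling per
increment. Depth scaling multiplies per-stage repeat counts (extra
repeats run at stride 1), the convention under which the doubling law
actually holds; appending whole stages at the lowest resolution would
under-scale the cost.

The default extractor is a compact seven-stage stack alternating 3×3 and
5×5 kernels with interleaved stride-2 stages and a final width of 64 —
the extracted feature dimension. Weights are seeded He-uniform; the
random-weight extractor is the default test fixture (random deep features
are still class-discriminative on the synthetic images, which is all the
selection layer needs; training the extractor is out of scope here).

## Data preparation

`plan_balance()` computes per-class synthetic demands
($\max(0, \mathrm{target} - n_c)$, majority classes exempt);
`smote_generate()` draws a class sample $x$ uniformly, one of its
$k = 5$ nearest same-class neighbors $x_{nn}$ (Euclidean, raw vectors),
and returns $x + \delta (x_{nn} - x)$, $\delta \sim U(0,1)$. For images
the interpolation runs in flattened pixel space with values clipped to
the valid range — the only reading under which SMOTE "generates synthetic
images". Because oversampling before splitting leaks synthetic copies of
test-set neighbors into training, the pipeline balances the *training
partition only* by default; a literal whole-dataset mode exists for
comparison (`smote_mode = "whole"`).

Stratified splits use `floor(fraction * n)` per class for training with
the remainder to test. Published per-class train/test tables for these
benchmarks are internally inconsistent with any single rounding rule, so
one rule is fixed and documented.

## The synthetic fixtures

Feature mode plants `n_informative` columns whose class means are shifted
by `effect_size` (default 3) noise standard deviations, each informative
column separating one class (assigned cyclically) from the rest; all
remaining columns are pure noise. With three classes and three
informative columns every informative column is necessary, which gives
wrapper selection an exactly known ground truth. Image mode renders
skin-toned backgrounds with a colored elliptical blob and a sinusoidal
texture whose color, radius and frequency depend on the class.

What these fixtures do *not* emulate: hair and ruler artifacts, specular
highlights, inter-device color shifts, ambiguous lesion borders, label
noise — the things that make real dermoscopy hard. Passing tests
demonstrate that the optimizer, objective, blocks and statistics are
implemented correctly and interact as designed, not that the pipeline
would reach any particular accuracy on clinical data.

## Statistics

The run-statistics suite reports MIN/MAX/mean/Std over independent runs,
the bias-corrected sample excess kurtosis

$$\mathrm{Kur} = \frac{n(n+1)}{(n-1)(n-2)(n-3)}
  \sum_i \Bigl(\frac{x_i-\mu}{s}\Bigr)^4 - \frac{3(n-1)^2}{(n-2)(n-3)}$$

with $s$ the sample ($n-1$) standard deviation, and the Matthews
correlation. The binary MCC is the standard four-count formula with
zero-denominator terms defined as 0 (the constant-predictor convention);
for $K > 2$ classes the default is the macro average of the $K$
one-vs-rest binary coefficients — it uses only the binary formula — with
the generalized multiclass statistic available as an option. Per-class
metrics with zero denominators are reported as missing (`NA`), never
silently as 0; perfect-class rows make this convention load-bearing.
ANOVA-F and two-sample-t comparisons of optimizer variants delegate to
the standard library routines with equal-variance pooling.

## Problem sizes and reproducibility

Every stochastic component is seeded, and per-run seeds in Monte-Carlo
mode derive as `base_seed + run_index`, so whole-pipeline runs are
bit-reproducible. The shipped study sizes are desk-scale by design:
swarms of 30 particles over 100–500 iterations, tables of 200 samples
with 12–64 features, image batches of around 200 at 32×32 — large enough
for the exhaustive-oracle and planted-recovery checks to be decisive,
small enough that the full suite runs in minutes on one CPU. The
published headline accuracies on HAM10000/ISIC 2019/MSLD v2.0 require
GPU-scale training on the external datasets and are deliberately out of
scope; what this package reproduces exactly is the arithmetic of the
published worked examples and the behavioral contracts of every
component.

## Known limitations

* The wrapper fitness inherits the variance of a single internal
  validation split; cross-validated fitness would be slower but smoother.
* Macro one-vs-rest MCC and the generalized multiclass MCC can disagree
  on imbalanced tables; both are exposed, one had to be the default.
* The random-weight extractor is a fixture, not a trained model; its
  features are discriminative but far from optimal.
* SMOTE in pixel space produces ghosting artifacts for images of rigid
  structure; for dermoscopic blobs this is mild, for other modalities it
  may not be.
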