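---
title: "Sparse ordinal logistic regression for high-dimensional decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse ordinal logistic regression for high-dimensional decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseolr)
```

## The problem

Many decoding targets are *ordinal*: discrete, ordered, with undefined
between-class distances — subjective ratings, graded stimulus levels, the
mean contrast of an image patch. Treating them as nominal classes throws
away the order and inflates model complexity; treating them as continuous
responses invents a metric that the data do not define. The cumulative-link
ordinal model threads this needle: a single latent score is compared against
ordered thresholds, so all decision boundaries share one normal vector and
the model has far fewer effective parameters than a multiclass classifier.

In the intended application — decoding from multivoxel activity patterns —
the feature vector has hundreds to thousands of voxels while only tens to
hundreds of training samples exist, so simultaneous feature selection is as
important as the link function. `sparseolr` combines the two: ordinal
logistic regression estimated under an automatic-relevance-determination
(ARD) prior that drives the weights of irrelevant features to exactly zero.

## Model

For features $x \in \mathbb{R}^D$ and an ordinal label $y \in \{1,\dots,C\}$,

$$z = w^\top x + \varepsilon, \qquad
  y = c \iff \mu_{c-1} \le z < \mu_c,$$

with standard logistic noise $\varepsilon$, strictly increasing thresholds
$\mu_1 < \dots < \mu_{C-1}$ and the conventions $\mu_0 = -\infty$,
$\mu_C = +\infty$. The likelihood of a sample with label $c$ is
$F(\mu_c - w^\top x) - F(\mu_{c-1} - w^\top x)$ where
$F(z) = 1/(1+e^{-z})$. Note the standard-logistic convention: the noise has
variance $\pi^2/3$, not 1; the link function above is the operational
definition. Prediction takes the class with the highest probability, ties
broken toward the lower class. This argmax rule coincides with reading off
the threshold segment of $w^\top x$ away from the thresholds (exactly so
for $C = 2$), but inside a narrow segment the switch point shifts — the two
rules are *not* identical in general, and the package implements the
argmax.

The priors are

$$w \mid \alpha \sim \mathcal{N}\!\big(0,\ \mathrm{diag}(\alpha_1^{-1},\dots,\alpha_D^{-1})\big),
  \qquad p(\alpha_d) = \alpha_d^{-1},$$

with a flat (infinite-variance Gaussian limit) prior on $\mu$. L2OLR
replaces the ARD prior by the isotropic $w \sim \mathcal{N}(0, \alpha^{-1}I)$
with a single estimated precision — a ridge-type baseline that never
produces exact zeros.

## Estimation

The MAP solution has no closed form; estimation uses a mean-field
factorization $q(w,\mu)\,q(\alpha)$ with a Laplace (Gaussian) approximation
for $q(w,\mu)$. Each outer iteration of `fit_solr()`:

1. takes one damped Newton ascent step in $w$ (backtracking line search on
   the $\alpha$-penalized log likelihood) and one in the thresholds;
2. forms the Laplace posterior variances $S_{dd}$ from the inverse of the
   penalized Hessian $\mathrm{diag}(\alpha) + X^\top \Lambda X$, using the
   Woodbury identity when $D \gg N$ so the cost is $O(N^2 D)$;
3. updates the relevance precisions and prunes: a feature whose precision
   exceeds `prune_threshold` ($10^8$) is frozen at weight exactly 0 and
   dropped from subsequent Newton systems.

Thresholds are parameterized as $(\mu_1, \log \Delta_2, \dots)$ so their
ordering is maintained unconditionally; the Jacobian correction of this
reparameterization is omitted at the MAP point (the threshold prior is
flat, and the correction does not move the likelihood optimum
appreciably). Initialization: $w = 0$, $\alpha_d = 1$, thresholds at the
logistic quantiles of the empirical cumulative class frequencies.

**The precision update.** Two updates are implemented
(`fit_options(alpha_update = )`):

* `"mackay"` (default): $\alpha_d \leftarrow (1 - \alpha_d S_{dd}) / \bar w_d^2$,
  the MacKay/Tipping effective-degrees-of-freedom form used throughout the
  relevance-vector-machine lineage.
* `"vb"`: $\alpha_d \leftarrow 1 / (\bar w_d^2 + S_{dd})$, the posterior
  mean of the Gamma factor $q(\alpha_d)$ under the $\alpha^{-1}$ hyperprior.

The default is the MacKay form for a measured reason: on irrelevant
features the VB posterior mean grows only *linearly* per iteration (by
roughly the Fisher information of the feature), so no precision reaches the
prune threshold before the step-tolerance stopping rule fires and the fit
never contains an exact zero. The MacKay form grows geometrically on
irrelevant features and prunes them within tens of iterations, which is the
behavior that makes the method a feature selector at all. Both updates are
exposed so the difference is inspectable.

**Stopping.** The outer loop stops when the maximum absolute change across
$(w, \mu)$ is at most `step_tolerance` (default 0.001) or after
`max_iterations` (default 500). `objective_trace` records the log joint
over the active features at each iteration; it is not guaranteed monotone
across iterations because the $\alpha$ update and pruning change the
objective itself (each Newton step is guaranteed non-decreasing in *its*
objective by the line search, which is what the tests assert).

**Numerical safeguards.** Class probabilities are floored at $10^{-300}$
before logs, so the log likelihood is always finite; a $10^{-8}$ diagonal
jitter is added if a Cholesky factorization fails (logged); threshold
increments are capped so $\exp$ cannot overflow; precisions are capped at
$10^{12}$ so the prune test stays finite.

## Comparison estimators

* **SLiR** (`fit_slir`): ARD linear regression treating the label as
  continuous — Tipping-style conjugate updates, noise precision
  $\beta = (N - \sum_d \gamma_d)/\|\text{resid}\|^2$, features and response
  centered, intercept restored. Continuous outputs are assigned to the
  nearest label (`predict_slir_ordinal`), midpoints rounding down, clipped
  to $[1, C]$.
* **SMLR** (`fit_smlr`): softmax regression with a per-entry ARD prior,
  class $C$ fixed as the zero reference (the standard identifiability
  choice), unpenalized intercepts, per-class block Newton steps. Its
  decision boundaries are unconstrained, so it ignores the class order —
  the property the permutation test in the suite checks.
* **Elastic-net OLR** (`fit_elasticnet_olr`): penalized maximum likelihood
  with explicit $\lambda_1 \|w\|_1 + \lambda_2 \|w\|_2^2$ (two explicit
  penalties rather than a mixing ratio, since the parameterization was a
  genuinely open choice). The L1 term is smoothed as
  $\sqrt{w_d^2+\epsilon^2}$ and majorized by a quadratic, so each
  iteration is a reweighted ridge Newton step; $\epsilon$ anneals from 0.1
  to $10^{-8}$ (iteratively reweighted shrinkage). Stopping uses the same
  0.001 step tolerance. Weights below $10^{-6}$ are zeroed on exit for
  sparsity accounting. Unlike SOLR it has two hyperparameters the caller
  must tune.

## Simulation benchmark

`simulation_config()` defines the study conditions: five Gaussian classes
in $D$ dimensions sharing diagonal covariance with per-dimension SD 3.0;
the first class mean at the origin and each subsequent mean adding positive
increments — drawn from Exp(mean 1), or all 1.0 in `"fixed"` mode — in the
first 10 coordinates only; equal per-class allocation (remainders, never
needed for the canonical sizes, go to the lowest classes and are logged);
1000 test samples; Spearman rank correlation between true and predicted
labels as the score, with constant predictions recorded as `NA` and
excluded from means with a logged count rather than scored zero.

`run_sweep()` runs the two experiments — performance versus $D$ at
$N = 100$ and versus $N$ at $D = 1000$ — with a paired design: within a
repetition every algorithm fits the identical training draw and is scored
on the identical test draw. One master seed spawns per-repetition child
seeds, so any repetition can be replayed in isolation. Increment vectors
$h$ are resampled every repetition (the between-repetition variability is
part of the design; a fixed-$h$ variant is available through
`increment_mode = "fixed"`).

The package's own checks run this benchmark at desk scale: 20 repetitions
(not 100) at the hardest canonical point $D = 1000$, $N = 100$, and at the
easy point $D = 25$, $N = 2000$ where all four estimators converge to the
same accuracy. The feature-recovery check uses a deliberately
well-separated configuration — `noise_sd = 0.5` with the default
increments, i.e. adjacent-class Mahalanobis separation around 6, so class
overlap is negligible — defined once, here, as what "well separated" means
in this package; the benchmark default stays at the hard SD of 3.0.

## What the generator does and does not emulate

The Gaussian class-conditional generator reproduces the ordinal feature
geometry (monotone class means), the high-$D$/low-$N$ regime, and the
irrelevant-feature problem. It does not emulate spatial voxel correlations,
hemodynamic temporal structure, session effects, or heavy-tailed noise of
real recordings — so passing benchmarks here demonstrates correctness of
the estimators under the stated model, not effect sizes on real data.

## The contrast-decoding task

`enumerate_bases()` tiles the 10×10 stimulus grid with overlapping local
bases of shapes 1×1, 1×2, 2×1 and 2×2 (100 + 90 + 90 + 81 = 361
placements, row-major by top-left corner, 0-based). The mean contrast of
the binary pixels under a basis takes $hw + 1$ equally spaced values — 2,
3, 3 and 5 classes for the four shapes — and is the ordinal decoding
target (`mean_contrast_label`).

`generate_synthetic_session()` is a synthetic stand-in for a recording
session: random Bernoulli(½) binary images, and voxels that pool pixels
through Gaussian receptive fields (SD 1.2 px, centers uniform, weights
normalized), pass the drive through the saturating gain $u/(1+u/2)$, and
add Gaussian noise (default SD 0.15, about one signal SD for the
best-placed voxels). The saturating gain makes the mean response increase
monotonically but sublinearly with local contrast — the qualitative
response property that motivates ordinal rather than linear treatment. The
generator stores its RF weights so tests can audit ground truth. It makes
no claim of physiological fidelity.

Decoding (`train_local_decoders`) runs seeded, label-stratified five-fold
cross-validation per basis; reconstruction multiplies each basis by its
predicted contrast and combines them with per-pixel least-squares weights
learned from the training images (ridge-stabilized at $10^{-6}$), a
documented stand-in for the optimal basis combination of the original
reconstruction approach. The `identity_session()` configuration — one
noiseless voxel per pixel, identity gain — is the end-to-end oracle: every
image must reconstruct with spatial correlation 1.

## Known limitations

* The ARD fits perform *hard* selection. On weakly informative features
  whose evidence does not exceed the type-II threshold at small $N$, the
  precision diverges and the feature is lost, where an L1 path would
  retain it with a small weight. At the hardest benchmark point this costs
  rank correlation relative to the ARD-linear baseline (whose conjugate
  updates estimate a more stable direction from 100 samples), even though
  exact-label accuracy is comparable and the ordinal model dominates both
  its ridge counterpart and the order-blind classifier. The elastic-net
  estimator with well-chosen penalties illustrates the gap: soft
  thresholding at the same operating point retains most informative
  dimensions.
* On separable data the retained features' weights grow until the step
  tolerance stops them (the likelihood has no finite optimum there); the
  prior slows but does not prevent this. Predictions are unaffected in
  rank terms, but reported weight magnitudes at convergence should not be
  over-interpreted.
* `objective_trace` is diagnostic, not a convergence certificate (see
  above).
* The synthetic voxel generator is a caricature; no claim about real fMRI
  effect sizes follows from it.
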