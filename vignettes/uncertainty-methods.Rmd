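---
title: "Logit-space epistemic uncertainty: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logit-space epistemic uncertainty: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Binary clinical risk models are routinely validated with population-level
discrimination and calibration metrics, yet those say nothing about how much
evidence stands behind any *individual* prediction. A patient unlike anyone
in the training data can receive a confidently wrong risk estimate from a
perfectly calibrated model. Distinguishing *epistemic* uncertainty (reducible
lack of knowledge, high where training data are sparse) from *aleatoric*
uncertainty (irreducible outcome noise at a given feature vector) is what
makes per-case deferral possible: an epistemically uncertain case calls for
human judgment or more data, an aleatorically ambiguous one will not improve
with review.

`logituq` implements and compares three approximate Bayesian neural
classifiers that differ in how their functional prior is specified:

* **ENN** — a deep ensemble: M networks identical except for their
  Kaiming-uniform initializations; their outputs are particles from an
  *implicit* functional posterior.
* **BNN** — a variational Bayesian network with *radial* weight posteriors
  (location-scale with the noise direction normalized to the unit sphere and
  a scalar Gaussian radius), trained by maximizing the ELBO against a
  factorized Gaussian weight prior — again an implicit functional prior.
* **SNGP** — a spectral-normalized residual feature extractor feeding a
  Gaussian-process output head approximated with random Fourier features:
  an *explicit*, distance-aware prior over functions with a closed-form
  Gaussian latent posterior.

## Uncertainty measures in logit space

All measures live on the latent log-odds (pre-sigmoid output) rather than on
probabilities, which decouples them from the prior class frequency and from
outcome entropy. With `l1` the training prior log-odds
(`log(n1/n0)`) and `l1x` the posterior log-odds at an instance, the Bayes
factor is `K = exp(l1x - l1)`; `K = 1` is neutral evidence.

For a posterior over functions (ensemble members, BNN weight draws, or the
SNGP's closed-form Gaussian):

* **Evidential strength** `ES = |E[l1x] - l1|`, the deviation of the
  posterior-mean log-odds from the prior;
* **Total uncertainty** `u_tot = exp(-k ES)` in `(0, 1]`: equal to 1 at
  neutral evidence, tending to 0 under overwhelming evidence either way;
* **Epistemic uncertainty** `u_epi = 1 - exp(-k Var[l1x])` in `[0, 1)`:
  0 for a delta-distributed posterior, approaching 1 as the functional
  posterior widens without bound.

The decay rate `k` (default 1) only rescales the measures; every ranking —
and therefore every Spearman-based analysis in the package — is invariant
to it. The sample form uses the unbiased (n−1) variance across draws, which
matters at the reduced numbers of draws used at desk scale. Entropy-style
probability-space measures are deliberately not provided: they peak at
p = 0.5 and measure outcome uncertainty, not prediction uncertainty.

## Mean reversion as the behavioral criterion

For a predictor whose prior encodes local correlation and distant
independence (a GP with a distance-decaying kernel), the posterior
predictive at a query reverts to the prior predictive whenever nearby
observations carry no information — either because there are none
(epistemic extreme) or because their labels are pure noise (aleatoric
extreme). `gp_oracle` implements this argument exactly: an RBF-kernel GP
with per-point Gaussian pseudo-likelihoods whose posterior can be checked
against brute-force conditioning, a locality partition of the data around a
query, and `mean_reversion_check()`, which asserts that the latent mean
deviation decays and the variance returns to the prior along a ray leaving
the data support. The check asserts the *envelope* (near-third versus
far-third of the ray), not pointwise monotonicity: a GP mean legitimately
oscillates around the prior near the data edge before decaying.

The same Laplace-weighted GP is the exactness oracle for the SNGP head: a
ridge-penalized cross-entropy fit on random Fourier features is the MAP of
a GP classifier with kernel `k_RBF / lambda`, so on a small 1-D problem
with an identity backbone the SNGP's latent mean and variance must agree
with the exact GP up to the kernel approximation error of the features
(about `3/sqrt(D)`; ~1% observed at D = 4096).

## Model construction and numerical choices

No deep-learning framework is used: the networks are small and dense, so
forward passes, reverse-mode gradients, Adam, spectral normalization and
the radial reparameterization are implemented directly on matrix
operations.

**Backbone.** Fully connected ReLU layers (default three of width 16 for
the experiments here), Kaiming-uniform initialization with bound
`gain * sqrt(6 / fan_in)`, full-batch Adam by default (minibatching with
seeded reshuffling is available), early stopping on validation
cross-entropy with the best state restored. For the SNGP variant the hidden
stack is residual and every weight matrix is spectrally normalized below
c = 0.95 — each layer is a strict contraction, so feature-space distances
are controlled and the GP head's notion of "far from the data" is
meaningful. During training the top singular value is tracked by one
warm-started power iteration per step; because that estimate lags a fast
optimizer, the returned state is exactly projected with an SVD at the end.

**Ensemble.** Diversity comes only from initialization (and shuffling when
minibatching): the minimal mechanism stated for this family; bagging is
deliberately off. Predictions pool members as a Bayesian model average in
probability space; the logit draws feed the uncertainty measures directly.

**Radial BNN.** Each parameter tensor carries location `mu` and scale
`sigma = softplus(rho)`; a draw is `w = mu + sigma * (eps/||eps||) * r`
with `eps` standard normal of the tensor dimension and `r` a scalar
standard normal. The ELBO uses one weight draw per step, KL weight
`1/n_train`, and the KL estimated as the radial posterior's analytic
entropy (including the exact unit-radial constant per tensor dimension)
plus a Monte-Carlo cross-entropy against the `N(0, 1)` weight prior; the
estimator is unbiased and its gradients are exact (checked against finite
differences at 1e-10). Early stopping monitors the validation
cross-entropy of the location network `w = mu`. Prediction uses M = 200
weight draws by default.

**SNGP head.** `phi(h) = sqrt(2/D) cos(Omega h + b)` with `Omega` rows
`N(0, 1/l^2)` and offsets uniform on `[0, 2pi)`, D = 1024 by default
(4096 for oracle-equivalence checks). After Adam training of backbone and
head, the head weights are refined to the exact ridge-penalized
cross-entropy MAP by Newton iteration (the subproblem is convex; the
representer form keeps the solve at `n x n` when `n <= D`). This removes
stochastic-optimizer error from the GP mean so it is exactly the mode the
Laplace covariance assumes; without it the Adam solution sits tens of
percent from the MAP and the closed-form variance is inconsistent with the
mean. The latent covariance is then built once and Cholesky-cached, making
query cost independent of the training size.

Two covariance-update likelihoods are provided. The Laplace (binomial)
form `P = lambda I + sum_i p_i(1-p_i) phi_i phi_i^T` is the textbook
Laplace approximation and is what the exact-GP equivalence checks
exercise. The default for fitted models, however, is the Gaussian form
with unit weights, matching the reference implementation of this
architecture. The reason is scientific rather than numerical: the Fisher
weights `p(1-p)` vanish at the probability extremes, so the binomial
covariance accumulates little precision exactly where the loss surface is
flat — importing the same `1/(p(1-p))` loss-curvature artifact that biases
the implicit-prior families (see below) into the one model designed to
avoid it. Measured on the toy experiment, the binomial update drags the
epistemic-uncertainty/label-noise Spearman to about −0.55 and weakens the
density correlation to about −0.4, while the Gaussian update leaves noise
correlation near 0 and density correlation near −0.55.

**Probability link.** The SNGP predictive probability integrates the
sigmoid over the latent Gaussian with the standard `1/sqrt(1 + (pi/8) v)`
mean scaling; a plain sigmoid-of-mean mode exists. At `v = 0` the two
coincide; as `v` grows the adjusted probability shrinks toward 1/2,
which is exactly the mean-reversion behavior in probability space.

**Kernel length-scale.** The GP head is distance-aware only at the scale
of its kernel: a length-scale much larger than the feature-space data
diameter makes the kernel effectively global and the variance nearly
constant. The default is 2.0 on the ~25-dimensional encoded cohort; the
2-D toy experiment uses 0.5, roughly a quarter of its feature-space
diameter (~2), so that "sparse" regions of the unit square are actually
distinguishable. Setting this per problem is a modeling decision, not a
tuning knob: the rule is a fraction of the pairwise feature distance
scale.

## Synthetic data: what it emulates and what it does not

**Cohort generator.** Emulates the structure of the screening-trial
prostate-cancer mortality task: n = 3600 records, 7% positive prevalence,
three categorical features (3/4/2 levels) and four continuous ones, MCAR
missingness (5%/10%), and a linear-in-encoded-features ground-truth logit
whose intercept is calibrated by root finding so the realized mean risk
hits the target prevalence. Effect sizes were chosen once to give an
oracle AUROC near 0.87, in the range typical of clinical
mortality-risk models. The generator
stores its true logits, enabling calibration-against-truth tests
(generator self-calibration ECE < 0.02 at n = 10^4) and the
oracle-stratification ceiling reported below. It does *not* emulate the
real cohort's feature list, informative missingness, or survival-time
structure.

**Toy generator.** The unit square with class probability `p1(x0) = x0`
and training density `w(x1) = (0.25 + 1.5 x1)` normalized (dense edge 7x
the sparse edge), n = 4000 train and test, labels i.i.d. Bernoulli. Class
probability depends only on x0 and density only on x1, so aleatoric and
epistemic ground truth are statistically independent — the property that
lets the correlation analysis attribute a model's epistemic estimate to
data support versus label noise. The test set is uniform on both axes.
Slopes and sample sizes are package choices; they give clearly separated
density strata without extreme label imbalance.

Passing tests on these generators shows the *mechanisms* behave as
designed — it does not certify behavior on real cohorts, where feature
correlations, informative missingness and distribution shift are all in
play.

## Preprocessing and validation protocol

Categorical features one-hot encode over training-fold levels plus an
explicit "missing" indicator; unseen levels at transform time map to that
indicator with a warning. Continuous features are standardized with
training-fold statistics only and missing values imputed with 0 (the
post-standardization mean — the least informative fill) plus a missing
flag. The cross-validation plan is a stratified six-fold 4:1:1
train/validation/test partition built from per-class permutations cut into
six blocks: test blocks are disjoint and cover the cohort; each fold's
validation set is the cyclically next block. Prevalence is conserved
exactly when class counts divide by six and to within one record per
block otherwise. Only test-fold disjointness is guaranteed across folds;
validation blocks recur as training data in other folds, as the 4:1:1
ratio forces.

## What the experiments show

`analysis/01_toy_uncertainty.R` and `analysis/02_cohort_cv.R` run the two
experiments at desk scale (ensemble M = 50, D = 1024, widths 16; about
1 and 3.5 minutes respectively on one CPU) and write tidy CSVs under
`results/`. The headline contrasts, all computed by the scripts
themselves:

* All three families reach essentially the same discrimination and
  calibration on the cohort (AUROC ≈ 0.84–0.85, ECE ≈ 0.02) — population
  metrics do not separate them.
* Ranking pooled cross-validated test predictions by **total** uncertainty
  stratifies NLL positively for all families (SNGP ≈ 0.97 Spearman; the
  implicit-prior families are positive but weaker, 0.5–0.8, because their
  mid-range miscalibration inflates the NLL of moderately-uncertain
  windows; the analytic ceiling of this generator — true-risk predictions
  with true-logit ranking — is ≈ 0.95).
* Ranking by **epistemic** uncertainty splits the families: SNGP ≈ +1.0
  (its uncertain cases really are its worst-predicted), ENN and BNN ≈
  −1.0 — their "most epistemically uncertain" cases are their
  best-predicted ones.
* On the toy data the mechanism is exposed: ENN and BNN epistemic
  uncertainty tracks the *inverse* of label noise (Spearman ≈ −0.4 to
  −0.6 against `p1(1-p1)`) and only weakly tracks density, while SNGP
  epistemic uncertainty tracks data density (Spearman ≈ −0.55 against
  density, |Spearman| < 0.1 against noise) and reverts to its prior along
  rays leaving the data support.

The inverse-noise tracking of the implicit-prior families is the
loss-curvature artifact: under a second-order view the logit variance
scales like `1/(p(1-p))` (`curvature_profile()`), which is largest at
confident predictions — precisely where aleatoric noise is smallest. The
entanglement is therefore a strong *negative* rank correlation with noise;
describing it as "correlating with aleatoric uncertainty" refers to its
magnitude, not its sign.

## Known limitations

* Networks are small and full-batch-trained; conclusions are about
  mechanism, not about the attainable accuracy frontier.
* The radial BNN uses a single MC draw per training step and a fixed KL
  weight of `1/n_train`; no annealing schedule is implemented.
* The implicit-prior families' total-uncertainty stratification falls
  short of the oracle ceiling on the synthetic cohort (0.5–0.8 vs 0.95);
  this reflects genuine mid-range miscalibration of small ensembles and
  variational networks at this data size, not a metric artifact.
* The exact GP oracle covers the regimes the mean-reversion argument
  needs (Gaussian pseudo-likelihoods); it is not a general-purpose GP
  classification package.
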