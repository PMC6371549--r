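---
title: "Growing networks for serial-ECG classification: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing networks for serial-ECG classification: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rslpnet)
```

## The classification problem

A serial-ECG pair (baseline and follow-up recording of the same patient) is
reduced to 13 difference features: signed changes in QRS duration (ms), QT
interval (ms), maximal QRS- and T-vector amplitudes (μV), QRS- and
T-integral magnitudes (mV·ms), QRS and T-wave complexity (%), heart rate
(bpm) and T-wave symmetry (%), plus three *magnitudes*: the Euclidean norm
of the ventricular-gradient difference vector (mV·ms), the absolute QRS-T
spatial-angle difference (degrees, in [0, 180]), and the norm of the
J-vector difference (μV).  The magnitudes matter clinically: a pathology
that moves a feature *back toward* normal values (pseudo-normalization)
would cancel in a signed difference but not in a difference magnitude.
`compute_difference_features()` implements exactly this contract; the
magnitude computation is invariant to the coordinate frame of the
vectorcardiogram, so the frame convention never needs to be fixed.

Upstream signal processing (12-lead to VCG conversion, beat averaging,
landmark detection, the complexity and symmetry measurements themselves) is
out of scope; the package starts from per-ECG feature records.

## Networks, error function, optimizer

Networks are fully connected feed-forward sigmoid nets with 13 inputs and
one output in (0, 1); *every* neuron, including the output, applies the
logistic sigmoid.  Fresh parameters are drawn uniformly from [-1, 1].

Clinical cohorts are imbalanced (controls outnumber cases), so the error is
the class-weighted normalized sum of squares

$$E \;=\; \frac{\sum_i w(y_i)\,(o_i - y_i)^2}{\sum_i w(y_i)},
\qquad w(1) = \tfrac{N}{N_\text{case}},\; w(0) = \tfrac{N}{N_\text{control}},$$

with inverse-prevalence weights, so each class contributes equal total
mass.  Normalizing by the total weight (rather than by $N$) makes
$E \in [0,1]$ and comparable across datasets of different size and
prevalence; weight rescaling leaves $E$, its gradient, and hence all
training decisions unchanged (a tested invariant).  Training and validation
errors each use the weights of their own dataset, so both are calibrated
[0, 1] quantities.

Learning is full-batch scaled conjugate gradient (Møller's algorithm):
conjugate directions with a Levenberg–Marquardt damping term in place of a
line search.  Defaults follow the algorithm's standard recommendations
(σ = 1e-4, initial λ = 1e-6, restart to steepest descent every P iterations
with P the parameter count).  One *iteration* is one full-batch update
attempt; unsuccessful steps raise the damping and leave the weights — and
therefore the training error — unchanged, so the training-error trace is
non-increasing by construction.  Gradients are exact backpropagation,
verified against central finite differences at relative tolerance 1e-5 in
the test suite.  The forward/gradient kernel is compiled (Rcpp/Armadillo)
because the acceptance test below evaluates it up to 500 times per
candidate architecture.

**Early stopping.**  A learning phase ends when the validation error
exceeds its previous value (strict inequality, patience 1), at a safety cap
of 1000 iterations, or when training *and* validation sets are perfectly
classified at threshold 0.5.  Freshly structured networks may overshoot
once, so the first comparison of a phase is exempted by default
(`first_iteration_exemption`).  The parameters returned are those of the
minimum-validation-error iterate among the iterations actually run — not
the last iterate — except that a perfect-classification stop keeps the
perfect iterate.  Restricting the minimum to iterations ≥ 1 keeps the
growth loop's bookkeeping consistent: an accepted candidate's returned
training error is always strictly below its predecessor's.

The 0.5 decision threshold is the symmetric choice for outputs coded
0 = control, 1 = case; ROC analysis later sweeps the threshold anyway.

## The constructive procedure

`rslp_run()` starts from one hidden neuron, trains it, and then alternates
structuring with learning:

* **Enumeration** (`candidate_architectures()`): one neuron added to each
  existing layer, then a new trailing layer of width 1; candidates violating
  *at most three hidden layers* or *non-increasing widths* are discarded.
  Order is first layer, deeper layers, new layer.
* **Acceptance** (`accept_candidate()`): the grown candidate keeps all
  existing parameters; only the new neuron's parameters (and the new
  connections it induces downstream) are random.  When a new layer is
  opened, the old last-hidden-to-output weights can no longer exist and are
  redrawn; the output neuron keeps its bias, which is a property of the
  neuron rather than of any connection.  The candidate must strictly lower
  the training error after exactly one SCG iteration; otherwise the new
  neuron is re-drawn, up to 500 times.  The comparison benchmark is the
  existing network's post-learning training error (its minimum-validation
  iterate), matching the reading that new neurons must "decrease training
  error" relative to the network being grown.
* **Learning** (`learn_candidate()`): accepted candidates run a full
  learning phase; success means a final validation error no larger than the
  existing network's.  On failure the candidate is regrown from scratch
  (fresh random neuron, acceptance re-run).  The re-initialization budget
  is read from the stricter of the two published statements: at most 10
  total attempts.
* **Selection**: among successful candidates, the lowest validation error
  wins.  Stopping: all candidates rejected (criterion 1), or perfect
  training-plus-validation classification (criterion 2, guarding against
  overfitting).

These rules imply three invariants that the tests assert across dozens of
seeded runs: every instantiated architecture is valid; accepted-step
validation errors never increase; accepted-step training errors strictly
decrease; and consecutive accepted architectures differ by exactly one
neuron, so the final neuron count equals one plus the number of accepted
steps.

`rslp_optimize()` repeats the whole run `n_alternatives = 100` times with
independent, named seed streams and keeps the largest learning-set AUC.
AUC ties (common when several alternatives reach 1.0) are broken toward
fewer neurons, then lower validation error, then lower index — preferring
the most parsimonious of equally good networks.

## Data handling choices

**Splits.** Cohorts are split 50% learning / 50% testing, and the learning
part 80% training / 20% validation.  Splitting is stratified by class by
default: the published per-class counts of both clinical databases are
near-exact stratifications, and stratification is the only way to guarantee
both classes in a 10-pair validation set.  Per-class part sizes are rounded
to the nearest integer.  An unstratified mode exists behind a flag.

**Standardization.** Features are standardized by the training-set mean and
population SD before entering any network or logistic fit.  The features
span three orders of magnitude (hundreds of μV vs a few %); with initial
weights in [-1, 1], unscaled inputs saturate the first sigmoid layer and
gradients vanish.  The scaler is part of the model: it is fitted once on
the training set, stored inside every saved model, and applied at
inference, so raw-feature cohorts can be scored directly.  Zero-variance
features fall back to scale 1 with a warning.

**Seeds.** Every source of randomness descends from one master seed through
named child streams (`child_seed(master, "rslp-alternative-7")`), so a
single sub-result can be reproduced without re-running everything, and two
runs with the same master seed are bit-identical end to end.

## Baselines

The standard-method network (`train_standard_nn()`) shares the split, the
scaler, the weights, and the SCG/early-stopping code path with the
constructive runs — it differs *only* in applying a single learning phase
to a fixed architecture with all parameters random.  Whether the original
comparator used validation-based early stopping is not documented; sharing
the rule is this package's choice (it is also the conservative one, since
it treats both methods identically).

The logistic baseline maximizes the inverse-prevalence-weighted
log-likelihood (via `glm`, quasibinomial link to accept fractional
weights).  It is unpenalized; if the fit saturates (numerically 0/1 fitted
probabilities, non-convergence, or exploding coefficients — i.e.
separation), it is refitted with a tiny ridge (λ = 1e-8) and flagged.
On separable toy data this triggers by design and is reported by a warning.

## Evaluation

`roc_points()` sweeps the decision threshold over all distinct scores plus
±∞ sentinels ("score ≥ threshold ⇒ case").  `roc_auc()` is the
Mann–Whitney pairwise statistic with half-credit for ties, identical to the
trapezoidal area of the sweep; the test suite checks exact agreement with a
brute-force pairwise oracle.  DeLong confidence intervals and the paired
test for correlated AUCs use the structural-components formulation (via
pROC, with the direction fixed so AUC is never silently reflected); the
intervals are cross-checked against a stratified bootstrap.  Accuracy at
the equal-sensitivity/specificity point walks the sweep to the sign change
of sens − spec; an operating point where the two are *exactly* equal is
returned as is, otherwise the crossing is interpolated linearly between the
bracketing points.  The exact-point rule is the only one consistent with
degenerate sweeps (e.g. scores equal to flipped labels must give accuracy
0); interpolation-only rules give nonzero answers there.

Feature screening (`summarize_features()`) reports per-class
50th [25th; 75th] percentiles with two-sided Wilcoxon rank-sum p-values
(exact enumeration for small tie-free groups, tie- and continuity-corrected
normal approximation otherwise) and the conventional */**/*** stars at
0.05, 0.01 and 10⁻³.

## The synthetic generator

Only the marginal quartiles (Q1, median, Q3) of the 13 features, per class,
are published for the two clinical populations; `feature_quartiles()`
ships that table.  `fit_quantile_model()` turns one (Q1, median, Q3) triple
into an inverse CDF: piecewise linear through (0.25, Q1), (0.5, median),
(0.75, Q3), with tails continuing the adjacent segment slope (scaled by
`tail_factor`, default 1) and draw probabilities clamped to [0.001, 0.999].
Sampled cohorts therefore reproduce the published quartiles exactly in the
large-sample limit (a tested property at n = 10⁶).  Features are drawn
independently because nothing is published about their correlations;
physically non-negative magnitudes are clipped at 0 (the angle at 180)
with a warning above a 5% clip rate.  In the published table, one
control-group QT entry has its upper quartile printed below its lower
quartile — an evident sign typo, transcribed with the positive sign so the
quartile ordering holds.

What this generator does *not* emulate: inter-feature correlation
structure, within-patient pairing effects, tail shapes beyond the
quartiles, and measurement artifacts.  Tests that pass on these cohorts
validate the *algorithms* (growth rules, optimization, inference), not
clinical performance; the published testing AUCs of the real databases are
not reproducible from marginals and are deliberately not targeted.

Toy families are abstract covariate patterns in the 13-feature schema:
`separable` offsets classes by ±2 noise-SD along features 1 and 9, with the
noise on those two features truncated at ±1.5 SD — without truncation a
"separable" Gaussian cohort of 200 samples contains a boundary-crossing
sample about a third of the time, defeating the family's purpose of
exercising the perfect-classification stop.  `xor2d` places the class in
the exclusive-or of the signs of features 1 and 10 (linearly inseparable by
construction, learnable by a two-layer net), and `null` carries no signal.
Because xor2d is *defined* by sign patterns, toy cohorts do not enforce the
non-negativity of the magnitude features; the quartile-calibrated generator
does.

## Problem sizes

The packaged tests and the acceptance script run at desk scale, chosen to
exercise every code path with stable statistics: toy cohorts of 120–400
pairs, 10 alternatives per optimization in the ordering comparison (100
remains the default for real use), 20 seeded constructive runs for the
invariant checks, 10⁴ draws for generator calibration (median standard
error ≈ 0.2 ms for the QRS-duration feature), 10⁶ draws for the quantile
round-trip, and 2000 bootstrap replicates against the DeLong interval.

## Known limitations

* The constructive procedure is greedy; it never removes a neuron, and the
  acceptance benchmark makes growth increasingly hard as the training error
  approaches zero, so runs on easy data stop early and small.
* Strict patience-1 early stopping is aggressive on noisy validation sets;
  this is faithful to the design (and is precisely why the single-phase
  comparator underperforms), but users wanting longer training can pass a
  validation set equal to the training set, turning the stop rule into
  train-to-convergence.
* The exact SCG hyperparameters of the original implementation are not
  published; the defaults here are the cited algorithm's standard ones.
* Whether the original pipeline standardized inputs is unknown; this
  implementation always does, and stores the scaler with the model.
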