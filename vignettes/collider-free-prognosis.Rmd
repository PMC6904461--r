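---
title: "Collider-robust prognosis models from images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collider-robust prognosis models from images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(colliderfree)
```

## The problem

A convolutional network trained to predict survival from a medical image
uses every factor of variation that correlates with the outcome. When one
of those factors is a *collider* — a variable caused both by the disease
and by something that also drives treatment choice — conditioning on it
opens a backdoor path and biases the estimated treatment effect, no matter
how good the predictions look on observational data. The canonical example
implemented here: tumour size is driven by tumour aggressiveness (`u1`,
which worsens survival) and by patient fitness (`u2`, which drives
treatment choice). Size is therefore a pre-treatment collider; tumour
heterogeneity is an ordinary prognostic factor that a prognosis model
*should* use.

`colliderfree` provides the complete simulation laboratory for this
problem: a structural causal model (SCM), a synthetic nodule-image
generator, a feature-matching sampler that couples images to simulated
patients, a multi-task CNN whose last-layer activations are constrained to
be linearly independent of the measured collider, and post-hoc OLS
estimators of the average treatment effect (ATE).

## The structural causal model

With all second parameters standard deviations:

* `u1 ~ N(0, 0.7071)` — aggressiveness (latent)
* `u2 ~ N(0, 0.7071)` — fitness (latent)
* `z ~ N(0, 1)` — heterogeneity
* `x ~ N(u1 - u2, 0.05)` — size, the collider; `sd(x) ≈ 1`
* `t ~ Bern(invlogit(u2 - 0.5 + N(0, 0.25)))` — treatment
* `y ~ N(t - z - 2 u1 - 0.5, 0.05)` — survival; the true ATE is 1

The treatment noise enters the log-odds additively before the logistic
link: it models idiosyncratic preference, so every patient retains some
probability of either treatment. With these constants about 39% of
subjects are treated; the simulator reports the realized fraction as an
attribute rather than asserting any nominal value, because the equations
(not a summary of them) define the model.

Useful large-sample facts, all checked by the test suite: OLS of `y` on
`{t, u1, z}` recovers the ATE exactly; OLS of `y` on `{t}` alone is also
unbiased (no open backdoor path without conditioning); OLS of `y` on
`{t, x, z}` — conditioning on the collider — is biased downward (about
0.54 with noiseless regressors, about 0.65 with realistically noisy
ones); within the slice `|x| < 0.1`, `corr(u1, u2) > 0.9` even though the
latents are marginally independent.

## The synthetic image pool

The generator renders elliptical nodules (area drawn log-uniformly over
20–600 mm², eccentricity 0.6–1, random orientation, ±2 px centre jitter)
on 100×100 patches at 0.7 mm spacing. Intra-nodule texture is a smoothed
Gaussian field rescaled so that its within-mask variance equals a target
drawn uniformly over the heterogeneity range. The background emulates the
visual difficulty of chest CT: a smooth parenchyma-scale field, fine
acquisition noise, and sparse blob- and vessel-like structures whose
intensities overlap the nodule's; nodule contrast itself varies by ±35%
between patches, and the rim is blended over about one pixel.

Two properties matter and pull in opposite directions:

* **Measurement exactness.** Features measured *with* the mask are tight:
  `corr(target area, measured size) > 0.99` and
  `corr(target variance, measured heterogeneity) > 0.95` over a pool.
* **Visual difficulty.** Recovering the same quantities *without* the
  mask, from a randomly cropped 51×51 patch, is realistically imperfect.
  This inherent measurement error is quantified by the ground-truth
  network run (below) and is what makes the collider problem interesting:
  with implausibly clean images the collider becomes so predictable and
  so predictive that no unweighted regularizer can price it out.

Size is standardized for matching and losses as a z-score of log-area
(sizes are log-uniform here and approximately log-normal in real pools;
the raw-area z-score is heavily skewed and would saturate the matching of
the symmetric simulated `x`). Heterogeneity is z-scored on the raw scale.
Standardization constants always come from the training split only, as
does the global intensity normalization. Train/validation splits are
disjoint at the nodule level; validation subjects are matched only against
validation images.

Matching minimizes the Euclidean distance between the subject's `(x, z)`
and the standardized measured `(x', z')`, drawing with replacement, ties
broken by the lowest pool index. Over a default pool the matched features
track the simulated ones with `corr > 0.98`.

What the generator does *not* emulate: anatomical context (ribs, airways,
pleura), correlated size–texture distributions, annotator disagreement,
3-D structure, scanner effects. Passing tests on synthetic pools therefore
demonstrate the estimator's behaviour under a known, controllable
data-generating mechanism, not performance on real CT.

## The network

A VGG-style backbone: five 3×3 convolutions with 16 channels, ReLU after
each, 2×2 max-pooling after the first four (51 → 25 → 12 → 6 → 3; pooling
a 3×3 map again would be degenerate, and the flattened size of
16·3·3 = 144 fixes all downstream shapes). Then three fully connected
ReLU layers (144, 144, 12) with dropout 0.25, and a linear layer with
`n_k = 6` output activations. The affine head concatenates the treatment:
`ŷ = β₀ + β_t t + Σ βⱼ aⱼ`. Batch size 40, Adam with learning rate 0.001,
no weight decay. All of this is authored in the package (conv/pool kernels
in C++ via RcppArmadillo, orchestration in R); gradients are verified
against finite differences in the test suite.

Three loss terms per minibatch of size `m`:

* `L_y`: mean squared error of `ŷ`.
* `L_x`: mean squared error between the reserved first activation `a₁`
  and the standardized measured collider `x'`.
* `L_reg`: the independence hinge
  `max(0, MSE(x̄, x') − MSE(x̂ᵉᵍ, x'))`, where `x̂ʳᵉᵍ` is an in-batch OLS
  (with intercept) of `x'` on the constrained activations `a₂..a₆`. The
  OLS is solved in closed form with a ridge jitter of 1e-6; by default
  gradients flow through the full solution (a stop-gradient variant is a
  config switch — at the in-batch optimum the two coincide up to the
  jitter, which the tests confirm).

Training modes: *causal* (optimizes `L_y + w_x L_x + w_reg L_reg`),
*biased* (optimizes `L_y` only; the contrast model that freely conditions
on the whole image), and *ground-truth* (replaces the outcome with the
subject's simulated `x` or `z`; used to estimate the inherent measurement
error of the image pipeline, which in turn calibrates the noise added to
the regression baselines).

## Numerical and design choices

These are the places where the method as stated leaves the behaviour
genuinely open, and what this package chose:

**Head calibration with a burn-in.** The affine head is recalibrated at
the end of every epoch — after a five-epoch burn-in — by least squares
of the target on `(t, a)` over clean (eval-path) activations of a
training subsample (`head_refit = TRUE`, `head_refit_after = 5`). The
head *is* the linear-regression part of the model, and calibrating it
matters far beyond cosmetics: with an optimal head the outcome loss
depends on the activations only through their span, so duplicating
collider signal in the constrained slots (already present through `a₁`)
earns nothing and the regularizer can purge it. With a head left to Adam
alone, the scalar coefficients adapt over thousands of optimizer steps;
meanwhile the trunk moulds the constrained activations to deliver the
collider with whatever sign the stale head happens to have, and a large
leak (`R²(x' | a₂..a₆)` of 0.6 and more) persists. The burn-in exists
for the opposite reason: refitting from the very first epoch zeroes the
coefficients of still-uninformative slots, which removes the
exploration pressure that lets the trunk discover the prognostic
(heterogeneity) features in the first place. The refit solve is guarded:
near-constant activation columns get coefficient zero, the rest are
standardized and lightly ridged, so a degenerate column can never
inject exploding activation gradients into the trunk.

**Slot projection.** At every head refit, the final linear layer is
first re-expressed so that each constrained activation has zero sample
covariance with the measured collider over the calibration subsample
(subtracting the appropriate multiple of the collider slot from each
constrained column — a pure linear reparameterization that leaves the
activation span unchanged). With all covariances zero, the OLS of `x'`
on the constrained activations is identically zero there: the last-layer
linear-independence constraint is enforced directly, while the in-batch
hinge continues to measure and penalize any dependence that regrows
between refits.

**Regularizer gradient routing.** By default the hinge's gradient is
applied to the final linear layer only (`reg_backprop = "last_layer"`):
the constrained slots are allocated within the learned feature space,
while the shared trunk keeps learning content under the outcome and
collider losses. Propagating the purge through the whole network
(`"full"`) lets it reach features that the collider and prognostic
signals still share early in training; in this regime that collapses the
constrained slots to constants before they differentiate. Optional
weights `w_x`, `w_reg` on the collider terms exist as configuration
(default 1 — the plain unweighted sum). They matter because on
standardized `x'` the hinge penalty and the outcome benefit of carrying
the collider are almost exactly balanced in this SCM (both approach the
collider variance at full use), so enforcement by penalty alone sits on
a knife edge — the observation that motivated the projection design.

**Early stopping** monitors the mode's optimized total on the validation
split, with a patience of 15 epochs and restoration of the best epoch's
parameters (the method prescribes the criterion — stop when validation
loss increases — but no patience; a noisy minibatch monitor needs one).
Final partial minibatches smaller than `n_k + 2` are dropped: the
in-batch regression would be ill-posed.

**Estimation.** After training, activations are extracted along the
deterministic eval path (center crop, no flips, dropout off). The
CausalNet ATE is the `t` coefficient of OLS of `y` on
`{t, a₂..a₆}` fitted on the training subjects; the BiasedNet ATE uses all
six activations of the unconstrained model, so both variants are scored
under the same post-hoc procedure. Outcome MSE is always reported on the
validation subjects. Near-constant activation columns are dropped before
the fit (their coefficients are unidentified at the training scale and
can produce arbitrary out-of-sample predictions); exactly collinear ones
are dropped with a warning by the pivoted solver.

**Scale-mismatch sensitivity.** The measured collider can be re-measured
on the wrong scale before entering the losses:
`area → area` (power 1 on the positive scale), `diameter → volume`
(power 3), `volume → diameter` (power 1/3), each followed by
re-standardization with training-set constants. The positive scale is
reconstructed as `exp(x·σ_log + μ_log)` with constants corresponding to
the nodule's linear dimension (diameter-like, 4–25 mm across ±3 sd);
basing the mapping on the linear dimension keeps the power-3 scenarios
at the severity of a physical diameter-versus-volume mismatch
(`corr ≈ 0.8` between actual and measured scales) rather than an
exponential one. Because all three are strictly monotone, rank
information is preserved and the constrained estimator should be (and in
the reference runs is) robust to them — that robustness claim is exactly
what the sensitivity suite checks. The `(area, area)` pair re-measures on
the raw area scale, so it reproduces the main run's result statistically
rather than bit-identically.

**Outcome coupling ambiguity.** A treatment-only regression on this SCM
has a theoretical MSE of about 3.0 when `y` is generated from the
simulated `z`. Reference results report a lower value, which would arise
if `y` were generated after matching, from the matched image's `z'`. Both
couplings are implemented (`outcome_from_image`); the default keeps the
simulated `z`, and the discrepancy is documented rather than resolved.

## Problem sizes

The reference configuration simulates 3000 training and 1000 validation
subjects against a pool of 5015/1528 patches, trains with early stopping
(typically 20–40 epochs), and reproduces the main-results table with
three replicate seeds. `quarter_scale()` (750/250 subjects, a quarter
pool, 20 epochs) is the smoke-test configuration used throughout the test
suite; at that scale the constrained network reliably shows the *bias
ordering* (constrained ATE closer to 1 than the unconstrained one, with
the independence diagnostic near zero), while the full-scale run is
needed for the constrained model to also retain enough heterogeneity
signal to beat the treatment-only baseline on prediction error.

## Known limitations

* The equilibrium between prediction benefit and independence penalty is
  intrinsically close in this SCM; results at small scales have visible
  seed-to-seed spread, which is why replicate seeds are reported.
* The regularizer removes *linear* within-batch dependence only — as
  specified. A nonlinear encoding of the collider in the constrained
  activations would evade it; the post-hoc diagnostic would not see it
  either.
* One collider, one image per subject, 2-D patches only.
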