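---
title: "Automated tuning of 1D-CNNs for spectroscopic regression: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tuning of 1D-CNNs for spectroscopic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic data generator does and does
not emulate, the numerical choices, and the known limits. It states no
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Vis–NIR diffuse reflectance spectra (400–2500 nm) carry information about
soil composition; regression models map a spectrum to a property such as
soil organic carbon (SOC, g·kg⁻¹). 1D-CNNs are strong models for this task
but have dozens of interacting hyperparameters, and hand tuning is slow and
unreproducible. `spectratune` frames the whole design — preprocessing
channels, architecture, and training regime — as one search problem over a
tree-structured space, minimises a cross-validated error with a Bayesian
optimiser, and afterwards attributes performance variance to individual
hyperparameters.

## Parametric networks and shape arithmetic

A network is a sequence of *conv-blocks* (convolution → batch normalisation
if ON → activation → pooling if ON → dropout if ON), a flatten layer,
*FC-blocks* (dense → batch normalisation if ON → activation → dropout if
ON), and a final dense unit with linear activation. Binary *state*
hyperparameters gate the optional layers and the five input channels, which
makes the space conditional: pool size, stride, padding and type exist only
when the pooling state is ON, and block-level hyperparameters of block *i*
exist only when the block count is at least *i*.

Output widths follow the ubiquitous border conventions: `Same` padding
gives `ceiling(w / stride)` (symmetric zero padding), `Valid` gives
`floor((w - kernel) / stride) + 1` and is infeasible when the kernel
exceeds the input width. `build_architecture()` is a pure function from a
configuration to a layer table with exact widths and a parameter count
(conv: `(kernel·in_channels + 1)·filters`; dense: `(in + 1)·units`; batch
norm: `2·channels` trainable). Infeasible configurations raise a typed
condition rather than being silently repaired: the evaluating objective
converts it into a finite penalty so the optimiser receives an informative
signal, and no architecture is ever distorted behind the user's back.

## Preprocessing channels

Five candidate channels in fixed canonical order: reflectance R, apparent
absorbance A = log₁₀(1/R) (base 10, the chemometric convention), absorbance
first and second derivatives, and the SNV of absorbance. Derivatives are
central finite differences with one-sided differences at the two borders,
which preserves spectrum length so all channels stack into one array; the
second derivative is the first-derivative operator applied twice. No
smoothing window is involved — derivative smoothing parameters are not part
of the search space, and plain differences are the minimal choice at the
211-point working resolution. SNV uses the population (1/n) standard
deviation with a 1e-12 degeneracy tolerance.

Channels are z-standardised per channel before training, with statistics
fitted on the training side of each fold only and applied to the validation
side — a declared extension needed for stable gradient training, not a
property of the modelled instrument. Targets are likewise z-scaled inside
`train_model()` using training-fold statistics, and predictions are
returned in original units.

## The objective

The search minimises the mean RMSE over k cross-validation folds (k = 10 by
default; fold sizes differ by at most one). Each fold trains a fresh
network with the configuration's optimiser, batch size and epoch budget
under early stopping. Failures do not abort a search: infeasible builds and
diverged fits return a penalty of `2 × sd(target)` — strictly worse than
the trivial mean predictor — with a status flag, and the trial is recorded.

Early stopping holds out 15% of each training fold as a monitor set, stops
after 50 epochs without improvement (`min_delta` 0) and restores the
best-epoch weights; all three values are configurable and the epoch budget
from the configuration is an upper bound, not a commitment. Learning rates
are not searched: per-optimiser defaults are Adam and RMSProp 1e-3 and
Adagrad 1e-2, overridable through `training_settings()`. The LeakyReLU
slope is 0.01 and ELU's α is 1. Batch-norm running statistics use momentum
0.9. When a configuration's batch size exceeds a (small) training fold it
is clamped to the fold size.

The training engine itself is part of the package: vectorised base-R
forward and backward passes for every layer type, with the convolution
executed as one matrix product on an im2col expansion. Its gradients are
verified against central finite differences in the test suite, and training
is bit-reproducible given the seed.

## The search space

`default_cnn_space()` encodes the full space: five channel states; conv
and FC block counts; per conv-block filters [4, 64], kernel [2, 10], stride
[2, 10], padding, batch-norm state, activation ∈ {ReLU, LeakyReLU, ELU,
SELU, Swish}, pooling state with conditional pool type/size/stride/padding,
dropout state; per FC-block nodes [5, 256], batch-norm state, activation,
dropout state; one shared dropout rate per block type in [0, 0.5]; the
optimiser ∈ {Adagrad, RMSProp, Adam}; batch size [16, n]; epochs
[100, 1500]. Choices that the printed ranges leave open were fixed once and
made configurable: block counts default to conv ∈ [1, 4] and FC ∈ [1, 3];
pool size [2, 5] and pool stride [1, 3]; per-block hyperparameters are
indexed per block rather than shared across blocks, which is the more
expressive reading; state flags are modelled as two-category categoricals
so the optimiser and the importance analysis treat every discrete dimension
uniformly.

Uniform sampling draws each active hyperparameter uniformly over its
domain, parents before children. One corner of the flag cube is invalid
(all five channels OFF, prior mass 1/32); the sampler rejects and redraws,
so every emitted configuration validates, at the cost of a negligible
deviation from per-flag marginal uniformity.

## The TPE optimiser

After `n_startup = 20` uniform trials, each suggestion splits the history
at the γ = 0.25 quantile of the objective (at least one good trial; ties
broken by trial index), builds per-hyperparameter Parzen estimators for the
good (`l`) and bad (`g`) sets, draws `n_candidates = 24` candidates from
`l` respecting the conditional tree, and returns the candidate maximising
`Σ log l − log g` over its active dimensions — the expected-improvement
ranking. Conditional hyperparameters are estimated only from trials where
they were active; a side with no observations falls back to the uniform
prior.

Numeric estimators are Gaussian mixtures at the observed values, truncated
to the domain, blended with a uniform prior at weight 1. Bandwidths are
adaptive per observation — the larger gap to the neighbouring observation
(domain edges included), floored at 1% of the domain width and capped at
the full width. A pooled Scott-rule bandwidth was tried first and discarded:
at realistic history sizes it is close to the good-set spread, so sampling
from `l` barely concentrates and the optimiser's edge over random search on
the packaged surrogate was marginal; the neighbour-gap rule (the classical
Parzen-estimator choice for this algorithm) sharpens the mixture where good
observations cluster and roughly doubled the margin in paired benchmarks
run during development. Integer dimensions are sampled continuously and
rounded to the lattice; categorical dimensions use Laplace-smoothed
frequencies, `(count + 1) / (n + K)` at prior weight 1.

Two special cases are handled explicitly. On fully categorical spaces with
at most 512 enumerable configurations the candidate set is the complete
enumeration, so the suggestion is the exact argmax of the smoothed density
ratio — useful both for small real spaces and for oracle testing. And when
every completed trial carries the same objective value (for example nothing
but penalties so far), the split carries no ranking signal, so the
suggestion falls back to uniform exploration instead of modelling noise.

The random-search baseline shares the history schema — index, origin,
status, per-fold and mean objectives, elapsed time, full configuration —
so the two arms are comparable trial for trial, serialisable as JSON lines,
and resumable.

## The packaged surrogate objective

Optimiser studies should not require hours of network training, so
`surrogate_objective("quadratic")` maps a configuration to a deterministic
RMSE-like value in seconds. It first runs the exact shape arithmetic on a
211-point input and returns a flat penalty (30 g·kg⁻¹) for infeasible
architectures — the same feasibility structure the real objective has,
which is a large part of what separates a model-based optimiser from random
search on this space. Feasible configurations score a smooth bowl: quadratic
terms pulling epochs high, filters high, stride low and the first FC-block
wide, a logarithmic bowl on batch size, linear penalties on extra blocks,
and categorical offsets favouring Adam, Same padding, no pooling and the
derivative channels. Its minimum (≈ 5 g·kg⁻¹) mimics a well-tuned model;
its shape is an emulation, not a fit to any measured landscape.

## Functional-ANOVA importance

`encode_history()` keeps the independent (unconditional) hyperparameters —
they exist in every trial, so the design matrix is complete — with the mean
objective as the response; penalised trials are kept by default since they
mark bad regions, and can be excluded. `fanova()` fits a bootstrap ensemble
of CART regression trees (64 trees, minimum leaf 3, `mtry = ⌈d/3⌉`,
categorical splits by subset via the sorted-means construction). For every
tree and dimension the *exact* marginal predictor is computed by
integrating the tree's piecewise-constant function over all other
dimensions with cell-volume weights under independent uniform inputs — no
Monte Carlo — and the first-order importance is the variance of that
marginal divided by the tree's total variance, averaged over trees. Because
the functional-ANOVA decomposition is orthogonal, the per-tree fractions
sum to at most one; the remainder is reported as the higher-order
(interaction) share, and the out-of-bag R² reports how well the surrogate
explains the history at all. Two robustness choices are deliberate: rows
are canonically sorted before fitting so reports are invariant to trial
order, and the split-gain threshold is relative to node SSE so reports are
invariant to affine rescaling of the objective. Integer dimensions are
integrated on the continuous span widened by half a lattice step on each
side.

## The synthetic spectra generator

`generate_spectra()` emulates the *structure* of a continental-scale soil
spectral library: a smooth baseline rising towards the NIR, `n_peaks = 8`
broad Gaussian absorption bands (widths 2–10% of the spectral range) whose
depths are deterministic functions of the sample's target, i.i.d.
reflectance noise (sd 0.002), clipping to (1e-6, 1], and a lognormal target
with median 20 g·kg⁻¹ and log-sd 0.8 — a right-skewed law spanning mineral
to organic soils. Band depths saturate as `t/(t + 50)` by default so
carbon-rich samples cannot push reflectance negative; a `linear` link is
available for exactness tests where the target must be recoverable with
correlation 1. The default 4201-point grid (400–2500 nm at 0.5 nm) thinned
by strided 1:20 selection gives the 211-point working resolution; strided
selection (not block averaging) was chosen because it composes cleanly and
is consistent with the downstream shape arithmetic of the reference
architecture.

What the generator does **not** emulate: instrument artefacts and scatter
effects that motivate SNV in real data, correlated noise, nonlinear
target–spectrum confounding, geographic structure, and the heavy-tailed
outliers removed during real library curation. Passing tests on synthetic
data therefore demonstrate that the machinery is correct and that signal of
the modelled kind is recoverable — not that any particular accuracy will be
reached on a real library.

## Problem sizes used by the tests

The suite and the acceptance script run at desk scale by choice: 2-fold
cross-validation on 200 synthetic samples with a 15-epoch cap for the
end-to-end search; 60-trial budgets with 20 paired seeds for the
TPE-versus-random benchmark on the surrogate; 500-trial histories in 10
dimensions for importance recovery. These sizes make the full pipeline
reproducible in minutes on one CPU while exercising every code path the
full-scale workflow uses.

## Known limitations

- The training engine is CPU-bound base R: appropriate for the package's
  test and desk scales, not for a 17,000-sample, 1500-epoch search, which
  needs a GPU-backed reimplementation of `train_model()` behind the same
  contract.
- TPE models dimensions independently; interactions enter only through the
  good/bad split. This is the classical algorithm, but strongly coupled
  hyperparameters can defeat it.
- Importance is reported for independent hyperparameters only; conditional
  ones (e.g. pool geometry) would need group-level treatment.
- Learning rates and their schedules are not part of the space.
- Published full-library accuracies are not reproducible from this package
  alone: the underlying library and its curation are external, and the
  compute regime is different. The package's claims are the property-based
  ones its tests compute.
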