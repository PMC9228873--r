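---
title: "Latent motion embeddings and bandit-driven difficulty adjustment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent motion embeddings and bandit-driven difficulty adjustment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(motionbandit)
```

`motionbandit` models a rehabilitation scenario in which a patient draws
reference shapes with a hand-held controller and a game adapts its
difficulty to the patient's motor control.  This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic data can and cannot show.

## The data model

A *motion* is a 32 × 2 matrix of planar points with one of six shape
labels.  Real capture hardware is out of scope; `emulate_protocol()`
generates the collection protocol instead (10 participants × 6 shapes ×
3 repetitions × 3 sessions = 540 motions).  Templates are parametric
silhouettes — square, 1:2 rectangle, a quartic heart curve, the lemniscate
of Gerono, a circle, an equilateral triangle — centred at their centroid
and scaled to a unit bounding-box side.  Two layers of variability are
added: a per-participant "style" (small anisotropic rescale plus a rotation
drawn once per participant, σ = 3°) and a per-trial Gaussian jitter
(σ = 2% of the bounding-box diagonal).  These emulate between- and
within-subject variation; they do **not** emulate tremor spectra,
velocity profiles, or pathological movement patterns, so conclusions
drawn from passing tests concern the pipeline's mechanics, not clinical
validity.

### Resampling

`resample_trajectory()` places m points at equal increments of cumulative
arc length along the input polyline, the resampling convention of
point-cloud gesture recognizers; only this resampling step of that family
is used (no cloud normalisation).  Two candidate uniformity contracts were
considered: equal *chord* gaps in the output, and equal *arc* increments
along the input.  Exactly equal chords do not always exist on cornered
paths — the leftover path length is discontinuous in the chord length when
a chord can skip a concave bay — so the arc-length convention is used.  It
is exactly idempotent on inputs whose points are already uniformly spaced
(straight segments, closed curves sampled at uniform angle, polygons with
commensurate point counts), which is the case for every trajectory the
package itself produces downstream.

## Artificial databases

`build_label_set()` implements the four-step augmentation: draw starting
values for the horizontal stretch \(p_h\), vertical stretch \(p_v\)
(percent of the original extent) and rotation θ (degrees) uniformly from
the code's ranges; schedule each parameter over 20 steps toward neutral
(ratio 1, rotation 0); transform the source motion at each step; emit
three replicates of each with Gaussian coordinate noise.  Open choices
resolved here:

* **Schedule behaviours.**  "Linear" is an arithmetic progression.  The
  "random staircase" is defined nowhere, so it is implemented as a
  monotone piecewise-constant sequence: 2–10 plateaus at random change
  points, plateau values read off the linear progression, endpoints
  pinned.  Each of the three parameters draws its own behaviour; all three
  share one schedule index so a dataset is a single coherent progression
  toward the target.
* **Schedule direction.**  Index 0 is farthest from neutral and the last
  index is exactly neutral, so with zero noise the final matrix equals the
  source — this gives the decaying distance trajectories the bandit stage
  expects.
* **Noise magnitude.**  Unspecified; default σ = 2% of the transformed
  motion's bounding-box diagonal — small enough to preserve class
  identity, large enough to matter for generalisation.  Configurable.
* **Source pool.**  The stated dataset size of the source pool (54)
  equals one participant's motions, so augmentation draws its per-label
  source from a single participant, re-drawn independently for each of
  the 20 datasets.
* **Split arithmetic.**  The published counts (3 test datasets; folds of
  12 training + 3 validation over 5 folds) are followed literally even
  though they do not consume all 20 datasets; 2 datasets per database
  remain unused and are recorded in the split.

## The adversarial autoencoder

Motions are flattened row-major to 64-value vectors.  Encoder, decoder and
discriminator are dense networks sharing the configured hidden widths
(decoder reversed; discriminator topped by a single sigmoid unit), Glorot
initialisation, Adam at one learning rate for all three steps, minibatch
64, 2-D latent output.  Each minibatch takes three steps:

1. *Reconstruction*: minimise the mean squared error over all coordinates.
2. *Discriminator*: prior draws (label 1) against encoder outputs
   (label 0), encoder frozen.
3. *Generator*: encoder updated so the frozen discriminator scores its
   outputs as 1.  The generator loss is typeset identically to the
   discriminator loss in the source; it is implemented in the
   non-saturating convention (relabel fakes as real and minimise
   cross-entropy), the reading consistent with "the encoder confuses the
   discriminator".

The prior is six 2-D Gaussians at uniform angles on a circle — a polar
rose.  Its geometry is not specified numerically; defaults are radius 4,
radial σ 1.0, tangential σ 0.5 (petal-shaped, configurable).  The absolute
scale is immaterial to the method: distances and KL divergences scale with
it, so error magnitudes are comparable only within one prior geometry.
In semi-supervised mode the discriminator additionally receives the
one-hot motion label and prior draws come from the label's own component;
the encoder itself never sees labels.

Early stopping monitors the mean per-cluster KL divergence on the
validation fold in semi-supervised mode; in unsupervised mode cluster
assignment is ambiguous, so validation reconstruction error is used
instead.  The weights of the best validation epoch are returned.
Cross-entropy predictions are clamped to [10⁻⁷, 1 − 10⁻⁷]; non-finite
losses abort training with the history attached.

## Latent evaluation

The closed-form Gaussian KL divergence is computed in the direction
D(prior ‖ fitted); near-singular covariances (minimum eigenvalue below
10⁻¹⁰ of the largest) are regularised by +10⁻⁸ I with a warning.  k-NN
accuracy uses k = 10 and majority vote; vote ties are broken by the
smallest summed squared distance among the tied classes, then by label
order, making predictions deterministic.  The distance of an embedded
motion to its label centroid is the Euclidean norm (the typeset "squared
difference of 2-vectors" must be a scalar).  Centroids derive from the
full emulated cohort's embedding.  The three noise replicates of each
schedule point occupy consecutive iterations, so one artificial dataset
yields 60 iterations (20 × 3) per label.

## Bandit agents

Estimates start at the optimistic value Q₀ = 5.  Kalman posterior
variances start at σξ² + σϵ², a weakly-informative value on the model's
own noise scales (unspecified otherwise).  Arms with zero pulls receive an
infinite UCB bonus, forcing one trial of each arm; selection among
infinitely-bonused arms is uniform.  The UCB radius is the canonical
c·√(ln t / 2Nₖ).  The evaluator sees the full true reward vector to form
P\*(t) (softmax at temperature 2) while the agent observes only the pulled
arm; the error term uses the estimates the agent acted on at iteration t.

Free parameters default to the minimisers of the mean cumulative error at
the horizon found by `grid_search()` over the published grids on code-X
reward sequences — the selection procedure the method prescribes (its
outcome is not published legibly, so the package ships the outcome of its
own run; `bandit_selected_params()` documents the values and any grid can
be re-searched).

## Genetic search

Fixed-length integer genomes index the hyperparameter vocabulary (layer
count, width pattern, base width, activations, learning rate, dropout).
Decoding clamps the base width so decreasing/increasing patterns stay
inside {4…512}.  Tournament size defaults to 3 (only the number of
selected parents is specified).  Elitism of one is added so the best
fitness is non-increasing — standard practice, and it makes the
monotonicity property testable.  A failed fitness evaluation scores
infinity rather than aborting the run.  Fitness for real searches is the
cross-validated mean cluster KL at a reduced epoch cap.

## Problem sizes

The package's reference experiments (test suite and
`scripts/acceptance.R`) use one fold of one XYR database, networks of two
64-unit hidden layers, at most 60 epochs with patience 12, three training
replicates per mode, and 30 episode runs per bandit agent (3 test
datasets × 10 seeds).  These sizes give stable qualitative orderings —
semi-supervised ≥ unsupervised k-NN accuracy; Kalman–Thompson below
Boltzmann-UCB error — while keeping a full run in the minutes range on a
single CPU.  The published full-scale accuracies depend on the real
captured dataset and are not reproduced by the synthetic protocol.

## Known limitations

* Synthetic motions are geometrically, not biomechanically, realistic.
* The unsupervised early-stopping metric (validation reconstruction) does
  not directly target cluster quality, so unsupervised KL values are
  reported but not optimised.
* Error magnitudes from the bandit stage depend on the latent scale set by
  the prior radius; comparisons are meaningful between agents under the
  same embedding, not across embeddings.
* The deposited capture data's on-disk layout is undocumented, so the
  reader for it is a guarded stub; converted CSV in the package's motion
  schema is the supported interchange format.
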