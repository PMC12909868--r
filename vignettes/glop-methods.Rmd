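---
title: "Modeling dyadic approach-avoidance movement with glopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dyadic approach-avoidance movement with glopr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

glopr implements a generative model of how one agent moves relative to
another on a screen, together with the machinery needed to invert that model
in real time: a simulator, an amortized neural estimator of the model's
latent parameters, and classifiers that read out an agent's latent goal
(Attack, Avoid or Inspect) from partial trajectories. This vignette explains
the model, the design choices behind the implementation, and what the
package's tests do and do not establish.

## The generative model

Two agents move on a `r 1920` x `r 1080` pixel screen sampled at 60 Hz; the
maximum separation is the diagonal, `dist_max` ≈ 2202.9 px. The participant
agent is driven by a *motivational vector* that blends three components,
weighted by non-negative weights `w_d`, `w_s`, `w_p` that sum to one:

- **Preferred distance** (local objective). With `t̂` the unit vector from
  participant `p` toward opponent `o`, the component is
  `v_dist = (‖p − o‖ − d · dist_max) · t̂`. The free parameter `d ∈ (0, 1)`
  is the preferred separation as a fraction of the diagonal: the agent is
  pulled toward the opponent when too far and pushed away when too close,
  with force proportional to the discrepancy. This is the classic
  approach-avoidance equilibrium: gradients intersect at `d · dist_max`.
- **Spatial preference** (global objective). A 50 x 50 grid of cell centers
  tiles the screen. Each cell `g` scores
  `D(g) = (dist_max − |‖g − o‖ − d · dist_max|) / dist_max ∈ [0, 1]`,
  peaking on the ring at the preferred distance from the opponent. The
  component is the normalized resultant
  `v_spatial = (1/N) Σ_g D(g)^s (g − p)`, where the sensitivity exponent
  `s > 0` sharpens (`s > 1`) or flattens (`s < 1`) the preference gradient.
  This lets the agent care about *where on the screen* it is — e.g. escaping
  a corner — independently of the direct vector to the opponent.
- **Pace matching**. `v_pace` copies the opponent's most recent per-frame
  displacement, letting the agent aim at where the opponent is heading
  rather than where it is.

The two positional components are discrepancies measured in pixels, while
pace matching is already a per-frame velocity; the simulator converts the
former into an intended joystick velocity through a proportional control
gain before the blend, `v_motiv = κ (w_d v_dist + w_s v_spatial) +
w_p v_pace`, with `motiv_gain` κ defaulting to 1/60 per frame (the agent
aims to close a discrepancy in about one second at 60 Hz). The gain is the
package's resolution of a genuinely unstated piece of the task physics:
without it, a typical discrepancy of several hundred pixels would demand a
physically impossible single-frame jump, and the joystick speed cap alone
would then bind on essentially every frame — collapsing the dynamics to
direction-only movement in which the autocorrelation and the motivational
weights leave almost no measurable trace (an oracle lag-1
velocity-autocorrelation feature correlates under 0.3 with the generating
autocorrelation in that regime). With the gain, intended speeds vary
smoothly over the joystick's range, the discrepancy magnitude stays
informative ("greater discrepancy, faster movement"), and the saturation
cap binds only for extreme discrepancies.

Gaussian motor noise with per-axis SD `v · ‖v_motiv‖` is added (faster
intended movement is executed less precisely; `v ≥ 0` scales it), and the
executed step blends the previous step through the autocorrelation weight
`a ∈ (0, 1)`:

```
v_traj = a · v_prev + (1 − a) · (v_motiv + noise)
```

The step is capped at `max_speed` (default 10 px/frame, emulating joystick
saturation) and positions are clamped to the screen. Agents closer than
`collision_radius` (default 40 px) collide: the alive flag clears and both
agents freeze for the rest of the trial.

### Sign and normalization of the spatial component

Two details of the spatial term were genuinely open and are worth recording.
First, the component's sign: a literal reading of the summand as
`(p − g)` would push the agent *away* from high-preference cells,
contradicting the semantics of preferring good locations. glopr implements
attraction (summand `g − p`) by default and exposes
`glop_config(spatial_sign = "printed")` for the literal alternative form.
Second, the raw sum over 2,500 cells would dwarf the other components for
any non-trivial `w_s`, so glopr divides by the cell count; this makes the
three motivational components commensurate in pixel units, and the
sensitivity exponent rather than the grid size controls the component's
scale. Grid indices are mapped to pixel cell centers
(`(i − ½) · width / 50`, `(j − ½) · height / 50`) so that all vectors share
pixel units.

### Numerical evaluation of the preference grid

Within one trial, `d` and `s` are fixed and the cell score depends only on
the cell's distance to the opponent. The bulk simulator therefore tabulates
`D(r)^s` on a 4,096-point radial grid per trial and interpolates linearly;
the interpolation error is below 1e-6 relative (about 1e-5 px on the
resultant), orders of magnitude under the motor-noise floor. The exported
`spatial_vector()` always evaluates the power exactly, and the test suite
pins it to a naive double-loop oracle at 1e-10.

## Opponent profiles

The opponent is scripted, not goal-driven: *Aggressive* heads straight for
the participant, *Shy* straight away, *Curious* holds a 200 px standoff
(the same distance-keeping rule as a GLOP agent with `w_d = 1`),
*Defensive* holds the midpoint between the participant and a hidden screen
location drawn uniformly per trial, and *Wandering* follows a persistent
random heading with wall avoidance. Opponent kinematics (6 px/frame,
Gaussian heading noise with SD 0.2 rad, heading persistence 0.95) are
package defaults chosen to produce plausibly brisk, smooth movement at
60 Hz — the original task's opponent code is not part of this package — and
all are exposed in `glop_config()`.

## The data factory

Training data for amortized inference are prior-predictive simulations:
parameters drawn from `d ~ Beta(0.3, 0.5)`, weights from three independent
`Gamma(2, 2)` draws normalized to the simplex, `a ~ Beta(5, 1)`,
`s ~ Gamma(2, 2)` and `v ~ Gamma(2, 5)`. Gamma entries are read as
shape/rate (means 1 and 0.4); the rate reading keeps the weights
exchangeable and movement variability modest. Trials that collide on the
very first time step are discarded. Each remaining trial is censored to an
independent uniform draw on {2, ..., 600} frames — censoring is what forces
the networks to operate on partial data and hence enables real-time
inference. The censoring ceiling defaults to the full 10 s trial because no
other ceiling is privileged. For efficiency the factory simulates each trial
directly to its censor length (the draw is independent of the trajectory and
the dynamics are causal, so this is distributionally identical to
simulating 600 frames and truncating).

Goal-labeled data for the classifiers are synthesized through a
goal-conditional parameter map: Attack draws `d ~ Beta(1, 9)` (close
preferred distance), Inspect `d ~ Beta(4, 8)` (intermediate), Avoid
`d ~ Beta(9, 3)` (far), implementing the expected ordering of preferred
distance across goals; other parameters follow the shared prior. The map
can additionally skew the motivational-weight distribution per population
(`label_param_map(w_shape = ...)`), expressing player pools whose behavior
leans on one motivation component — a goal that is carried by a weakly
weighted component is barely visible in trajectories, which matters when
constructing deliberately separable test populations. Trials are
grouped into simulated "participants" that share one parameter draw per
goal, so train/validation/test splits at the participant level preserve the
leakage structure that real participant-level splits guard against.

## Input encoding and the estimator

Each censored trial is encoded as a 5 x 138 matrix. Column 1 carries five
summary statistics: the opponent profile code (1-5), the circular mean and
circular variance (1 − R) of the direction angle of the participant-to-
opponent vector, and the mean and variance of the per-frame approach index
(the signed cosine between the participant's step and the direction to the
opponent: +1 approaching, −1 avoiding). Columns 2-138 carry the
`(alive, p_x, p_y, o_x, o_y)` series resampled to 137 points by linear
interpolation (nearest neighbor for the binary alive flag). Resampling is
how variable censored lengths (2-600 frames) are reconciled with the fixed
input shape; the frame rate implied by each column therefore varies across
trials, which is one reason fine-timescale parameters are harder to
recover from long trials' decimated series.

The estimator is a gated recurrent unit layer as wide as the input sequence
(138), followed by fully connected layers of 150, 50 and 15 units with
swish activations, dropout (p = 0.5) after the first swish layer, and a
linear head. Internally, before z-scoring, the recurrent layer's input is
preconditioned with four *delta channels* — first differences of the
position series, normalized per trial to unit RMS — the sequence-modeling
analogue of delta features in speech processing. The preconditioning
matters because per-frame displacements are roughly two orders of
magnitude smaller than the cross-trial spread of positions, so after any
affine input normalization the velocity-scale structure (which carries the
autocorrelation parameter) is numerically invisible to a recurrent learner
at practical training budgets; with explicit delta channels a single-task
control experiment recovers the autocorrelation parameter where the
unaugmented network never leaves zero. The public input contract is
unchanged — the deltas are derived inside the estimator.

The network is trained with Adam (learning rate 1e-3, batch 8,
gradient-norm clip 5, update-gate bias initialized to +1 so the recurrent
state starts with a multi-step memory timescale) on mean squared error
over *transformed* parameters —
logit for the doubly bounded `d`, `w_d`, `w_s`, `a`; log for the positive
`s`, `v` — so inverse-transformed predictions always respect the
theoretical ranges. `w_p` is reconstructed as `1 − w_d − w_s`. The head
has six outputs: recovery is reported for six quantities (d, w_d, w_s, a,
s, v), so the spatial weight is estimated explicitly rather than left
implicit. Inputs and targets are z-scored with statistics fit on the
training split only; an 80/20 random split provides validation curves.
Boundary parameter values are clipped to [1e-6, 1 − 1e-6] before the logit.

Monte-Carlo dropout provides approximate posteriors: 100 stochastic forward
passes with the dropout layer active yield 100 draws per parameter, whose
means and variances summarize estimation uncertainty. With dropout disabled
the network is deterministic, which is what the recovery analyses use.
Since there is no deep-learning dependency in this stack, the GRU,
backpropagation through time, swish, dropout and Adam are implemented in
the package's C++ core; the test suite verifies the analytic gradients
against central finite differences at 1e-5 relative tolerance and checks
optimizer sanity by memorizing small data sets.

## Goal classifiers

Five classifiers share one fully connected trunk (100, 60, 30, 20, 10, 3
units, swish, dropout 0.5 on the first layer, softmax head) and differ in
input: posterior mean/variance features from the estimator (12 inputs), the
resampled position series through a GRU front end, the five summary
statistics, or — for the two ensembles — the concatenated class
probabilities of two frozen, separately trained component networks (no
joint fine-tuning, matching the reading that ensembles consume component
*predictions*). Time-series classifiers count training "iterations" as
minibatch updates with validation every 100 updates; feature classifiers
count epochs with validation each epoch. Applied to every prefix of a trial
at the sampling rate, the classifiers perform real-time intent inference;
accuracy is expected to rise with prefix length as evidence accumulates.

## Evaluation

**Parameter recovery.** Pearson correlations between generating and
estimated parameters, overall and binned by censored length, computed on
the natural scale. Bins with fewer than 3 trials or zero variance are
undefined (`NA`), never zero. Recovery is expected to be strong for the
local objectives (`d`, then `a` and `w_d`), moderate and
length-dependent for the global ones (`w_s`, `s`), and weak for `v`:
movement variability is estimated despite poor identifiability so that it
absorbs residual noise rather than contaminating other parameters.

A package-level caveat on identifiability: reference regressors trained on
rich engineered kinematic features (an oracle ceiling, not part of the
deliverable pipeline) show that under this simulator's conditions the
spatial sensitivity exponent `s` carries very little recoverable signal at
desk scale, the motivational weights are only moderately identifiable, and
movement variability is *partially* identifiable. These ceilings are
properties of the generative conditions (priors, joystick physics,
censoring), not of the estimation network, and they bound what any
training procedure could achieve on these data.

**Posterior predictive checks.** Given fitted parameters and the observed
opponent path, the package simulates the participant's mean trajectory
(noise disabled, so the check is deterministic given the parameters — the
prediction is the model's expected path, not one noisy realization),
resynchronizing the predicted position and step vector to the observed
trajectory every 4 frames. Fit is the mean squared pixel distance within
each 66.67 ms segment, averaged per trial, aggregated by goal and profile
as means and medians, optionally after trimming 0.5% of each tail of the
pooled distribution (99% retention) because prediction errors are strongly
right-skewed. The closed-loop property — parameters estimated from a
trajectory predict it better than fresh prior draws do — is what the test
suite asserts.

## Problem sizes and reproducibility

The package's standard evaluation, mirrored in `scripts/acceptance.R`,
uses 10,000 censored training trials (2,000 per profile), 15 training
epochs and 4,000 test trials, with a 20,000-trial test set for the
variability check; this scale runs in well under half an hour on a single
core while already exhibiting the identifiability structure discussed
above. Larger simulation sets and longer training continue to improve the
weaker parameters (the amortized estimator is data- and step-hungry), so
the reported correlations should be read as what this scale achieves, not
as the method's asymptote. Unit tests use much smaller sizes. Every random quantity — prior draws, starting
positions, censoring, network initialization, minibatch order, dropout
masks — flows through R's RNG, so a single `set.seed()` reproduces any
run bit for bit, including the C++ internals.

## What the synthetic data do not show

The simulator emulates GLOP-driven motion against scripted opponents,
collisions, 10 s trials and random censoring. It does not emulate human
motor delays, joystick acceleration limits, strategic adaptation over
trials, or the empirical relation between assigned goals and parameters —
the goal-conditional map is an assumption with the right ordering, not an
estimate. Tests passing on synthetic data therefore establish that the
inference machinery is correct and well calibrated *under the model*, not
that the model captures any particular human data set; classifier
accuracies on synthetic goals are not comparable to accuracies on
empirical data.

## Worked example

```{r, eval = FALSE}
library(glopr)
set.seed(1)

trials <- generate_training_set(2000)
estimator <- train_estimator(trials, epochs = 5)
test <- generate_training_set(500)
recovery <- recovery_analysis(test, estimate_params(test, estimator),
                              test$censored_length)
recovery[recovery$bin == "overall", ]
autoplot(recovery)
```
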