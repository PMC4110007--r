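---
title: "Modeling 3D reaches as overlapping minimum-jerk submovements"
author: "submovekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling 3D reaches as overlapping minimum-jerk submovements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(submovekit)
```

## The model

submovekit treats a target-directed 3D arm reach as the superposition of a
small number of discrete *submovements*, each a minimum-jerk pulse with five
parameters: initiation time $t_0$, duration $D$, and a 3-vector amplitude
$\mathbf{A}$ (the net displacement it contributes, in cm). The per-dimension
velocity of one submovement is the canonical minimum-jerk bell

$$v_d(t) = \frac{A_d}{D}\,30\,\tau^2(1-\tau)^2,\qquad
  \tau = \frac{t - t_0}{D}\in[0,1],$$

zero outside its support, and the reconstructed reach velocity is the
pointwise sum over submovements. The $30\tau^2(1-\tau)^2$ shape integrates
to one, so $\mathbf{A}$ is exactly the displacement; position follows in
closed form from $10\tau^3 - 15\tau^4 + 6\tau^5$. Submovements are
hypothesized to implement discrete error corrections: the first pulse
undershoots the target and later pulses close the remaining distance.

The package implements the full pipeline around this model:

1. **Preprocessing** of recorded fingertip kinematics (100 Hz resampling,
   spline interpolation of marker occlusions up to 5 samples, exclusion of
   trials occluded longer than 50 ms, zero-phase 4th-order Butterworth
   low-pass at 10 Hz, central-difference differentiation).
2. **Decomposition** of each measured velocity trajectory into $N$
   overlapping submovements by bounded nonlinear least squares, for
   candidate $N$, with knee-point selection of the optimal count.
3. **Feature extraction**: causal kinematic features at each timestep /
   submovement onset.
4. **Prediction**: three small feed-forward networks that predict a
   submovement's initiation time, amplitude and duration from those
   features.
5. **Closed-loop simulation**: the three predictors chained so each
   network's inputs derive from the trajectory its own earlier predictions
   generated, yielding a corrective reach generator evaluated by target
   acquisition rate, VAF and RMSE against measured reaches.

## Decomposition

The objective minimised over the $5N$ parameters is

$$J = \sum_{d\in\{x,y,z\}} \int \big(\hat v_d - v_d\big)^2\,dt
      \;+\; \lambda \sum_d \int \Big(\sum_j |v_{j,d}| -
      \big|\textstyle\sum_j v_{j,d}\big|\Big)\,dt .$$

The second term is an overlap penalty: it is zero unless simultaneously
active submovements oppose each other in some dimension, and prevents the
optimizer from inventing large canceling pulse pairs. Its weight is
`lambda_overlap` (default 0.01) times the trial's peak speed, which puts it
on the same scale as the squared-error term. Durations are bounded below by
0.1 s — the approximate duration of a muscle-twitch force transient — and
above by `d_max` (default 2 s).

Optimization uses bounded quasi-Newton (L-BFGS-B) with analytic gradients,
multi-started from (i) a greedy initialization that repeatedly places a
submovement at the peak of the residual speed profile, (ii) warm starts
from the $N-1$ fit — one padded with a zero-amplitude submovement, which
makes the cost curve non-increasing in $N$ by construction, and one padded
at the residual peak — and (iii) `n_restarts` jittered perturbations.

**Model-order selection.** Both axes of the cost-per-$N$ curve are min-max
normalised to $[0,1]$ and the selected $N^*$ maximises the distance below
the descending diagonal — the point of maximum curvature, i.e. the smallest
model with near-asymptotic fit. Two numerical choices matter here:

* *Candidate range.* The knee can only resolve a submovement whose share of
  the normalised cost range exceeds roughly $1/(\max N - 1)$. With up to
  five submovements per reach, and the fifth carrying only about a tenth of
  the residual velocity power, the default range is $1\ldots14$, which
  keeps that last pulse above the resolution limit while leaving the
  geometry of the rule unchanged.
* *Parsimony guard.* When the smallest candidate already explains more than
  99.9% of the velocity power (`flat_tol = 1e-3` of the empty-model cost),
  the residual curve is numerical noise and the smallest $N$ is returned
  directly; ties in the distance criterion also break toward smaller $N$.

## Features and targets

All features are causal: they use only the start and target positions, the
submovements initiated at or before the current time, and the current
fingertip state.

* **Initiation (21 inputs, one logistic output):** the 15 pairwise
  distances among {start, target, fingertip, current submovement start,
  current submovement end, endpoint of all initiated submovements}, two
  binary in-target flags (fingertip now; planned endpoint), the remaining
  time in the current submovement, the same normalised by its duration, the
  time since its onset, and $e^{-20t}$ of that time, which emphasises the
  early period of each submovement. Labels are built per feature window:
  submovement $k$'s window runs from its onset to the later of its own end
  and the next onset plus 0.2 s, labelled 0 strictly before the next
  decomposed onset and 1 at and after it. Extending the window past short
  submovements' ends is necessary so that corrections arriving after the
  current submovement has finished still contribute uncensored positive
  rows. At inference the trigger is the first timestep whose output
  strictly exceeds 0.5.
* **Amplitude (24 inputs, three logistic outputs):** the six pairwise 3D
  differences among {start, target, current submovement start, endpoint of
  prior submovements}, each divided by DTTAPS — the Distance To Target
  accounted for by All Prior Submovements, i.e. the remaining start-target
  distance after summing all previously initiated amplitudes (the plain
  start-target distance for the first submovement, floored at 0.1 cm before
  division) — plus sign-preserving 4th roots of the three velocity and
  three acceleration components. Targets are the true amplitudes divided by
  the same DTTAPS, affinely mapped from $[-r, r]$ to $(0,1)$ with $r$ the
  largest absolute normalised amplitude in the training fold (stored with
  the model).
* **Duration (12 inputs, one logistic output):** the ten pairwise distances
  among {start, target, current submovement start and end, endpoint of
  prior submovements} plus 4th roots of speed and acceleration magnitudes.
  The current submovement's end position uses its amplitude, which is
  predicted before its duration in the closed loop, so the feature stays
  causal. Targets are durations divided by `d_scale` = 2 s, predictions
  clamped at the 0.1 s minimum.

"Current submovement start/end" positions are the planned trajectory (start
plus the closed-form displacement of the initiated submovements) evaluated
at $t_0$ and $t_0 + D$; "endpoint of initiated submovements" for the
amplitude and duration of submovement $k$ means the prior submovements
$j < k$.

## Networks and training

The architectures are fixed: 5 hidden units for initiation, 10 for
amplitude and duration, hyperbolic-tangent hidden activations, logistic
outputs. Training is full-batch Adam on mean squared error with early
stopping on a validation set (patience 200 epochs, cap 4000, learning rate
0.005) and L2 weight decay $10^{-3}$ on the connection weights — the
parameter tables carry only a few rows per reach, and the decay is what
keeps the parameter-rich amplitude network from memorising them. Inputs
are z-scored with statistics fitted on training rows only; at prediction
time inputs are clamped to the training range before standardisation, so
closed-loop states outside the training distribution (e.g. the exactly-zero
velocity of a simulated rest state, which the 4th-root transform would
otherwise map far from any training value) cannot drive the network into
extrapolation.

Cross-validation is 10-fold by reach, 80:10:10 into training, validation
and test groups; all rows of a reach share its fold, so no reach leaks into
the folds that score it. Reported metrics pool test-fold predictions from
all folds; initiation accounting is per feature window (a window whose
decomposition contains a next onset is a true positive when the network
fires and a false negative otherwise; a final window is a false positive
when it fires, a true negative otherwise), and initiation-time VAF is
computed over true-positive windows on times relative to the current
submovement's onset.

## Closed loop

The first submovement triggers automatically at $t = 0$ with predicted
amplitude and duration. At every subsequent 0.01 s step the initiation
features are rebuilt from the simulated state and the initiation network is
queried (one query per step); an output above 0.5 adds a correction with
predicted amplitude and duration. A reach succeeds when the fingertip has
stayed inside the 1.27 cm target sphere for a full second (sliding window
of consecutive in-radius samples), and fails at 3 s of simulated time or 30
submovements. After the last submovement ends the position holds constant.
Simulated and measured trajectories are compared on the measured grid over
the overlap of the two time bases, pooling the three dimensions into a
single VAF and a Euclidean-residual RMSE.

## The synthetic generator

Because the recorded participant datasets are not redistributed here, the
package ships a generator whose defaults encode the study conditions the
pipeline assumes: radial 3D reaches with start-target distances
$43.5 \pm 11.2$ cm truncated to 20–70 cm, 100 Hz sampling, 2–5 overlapping
submovements per reach with mean about 2.9, and band-limited velocity noise
(0.5 cm/s vector SD, low-passed at 8 Hz so preprocessing does not remove
it).

The generative policy is deterministic-plus-noise, and its structure is
what makes the pipeline testable end to end:

* The first submovement covers a U(0.6, 0.9) fraction of the start-target
  vector with 10° direction jitter — the undershoot the decomposition
  should find, with the direction scatter standing in for the unobservable
  motor state that limits how well any kinematics-only predictor can do on
  first submovements.
* Each corrective submovement *aims at the remaining vector*; with
  probability 0.48 it lands inside the target (uniformly within 1 cm of the
  centre) and the reach ends, otherwise it misses by a zero-mean error of
  magnitude `max(U(0.35, 0.55) × |remaining|, 5 cm)` and the sequence
  continues, closing by force at five submovements. The submovement count
  is therefore endogenous — a reach continues *because* a correction
  missed. Two consequences are deliberate: the conditional mean of the
  corrective policy is exactly "cover the remaining vector", which is the
  mapping a deterministic network can learn and the reason the trained
  closed loop converges onto the target; and the error floor keeps late
  corrections large enough (a few cm) for the knee criterion to resolve.
* Corrections launch at a U(0.6, 0.9) phase of the ongoing submovement's
  duration (±0.02 s), so onsets overlap the previous submovement and are
  predictable from its duration; durations follow
  $D = 0.22 + 0.011\,|\mathbf{A}| + \mathcal{N}(0, 0.02)$ s, clamped to
  [0.1, 1.5] s.

What the generator does *not* emulate: a neuromotor-noise process in the
executed trajectory (noise is additive measurement-style velocity noise),
joint-level biomechanics, the ~50 ms early-correction peak seen in human
data (onsets here are phase-locked to the ongoing submovement), and
history effects across trials. Passing the end-to-end tests therefore shows
that the pipeline recovers a learnable corrective policy under realistic
geometry and noise — not that it would achieve the same numbers on any
particular human dataset.

## Problem sizes and numerical choices in the shipped tests

The test-suite and acceptance-script corpora use 100 synthetic reaches per
run with one optimizer restart per candidate $N$ (the greedy and warm
starts already recover 9 of 10 submovement counts exactly; restarts are
kept configurable with a default of 5 for exploratory use). Teacher-student
checks of the training machinery use 5,000 random feature rows per
architecture with weight decay disabled, since the teacher is noiseless.
Tolerances asserted in tests come from the closed forms (displacement
conservation to 1e-6 cm in closed form, $O(dt^2)$ numerically) or from the
generator's design analysis (count-recovery and VAF floors).

## Known limitations

* Deterministic predictors reproduce the conditional mean of a stochastic
  policy: simulated reaches show less trial-to-trial variation than their
  generating policy, and the simulated submovement count is slightly lower
  than the decomposed one.
* Initiation-time VAF is intrinsically limited by the onset jitter of the
  policy; sensitivity/specificity are the more robust event metrics.
* The knee criterion under-counts when a reach's final correction carries a
  vanishing share of velocity power; the error floor in the generator makes
  this rare, but on real data the same bias would apply.
* The decomposition cost is non-convex; with pathological initialisation a
  fixed-$N$ fit can land in a local minimum. The nested warm starts
  guarantee the reported cost curve is non-increasing, but individual
  fixed-$N$ fits called in isolation carry no such guarantee.
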