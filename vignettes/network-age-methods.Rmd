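---
title: "Network age: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network age: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `netage`: the models and
their assumptions, the parameters that matter, what the synthetic colony
does and does not emulate, and the places where the design was genuinely
open and a choice had to be made.

## 1. From tracking data to affinity matrices

The raw substrate is a table of per-frame detections: tagged bee id,
timestamp, planar position in mm on the nest surface, body orientation in
radians, comb side, and a decoding confidence in [0, 1]. Combs are imaged
at 3 Hz alternating between sides, so one side is sampled effectively at
1.5 Hz; co-detections across sides are never treated as contacts, because
tags on opposite comb faces cannot touch.

Eight interaction modes are aggregated per day (24 h, non-overlapping):

* **proximity_count** — number of proximity events per pair. Two bees are
  in proximity when their tags are under 2 cm apart over at least 3
  consecutive co-detected frames. The event *count* is used, not the
  duration, to reduce the weight of bees resting next to each other. A
  co-detected frame at which the pair is too far apart breaks a run; a
  frame-slot gap above `max_frame_gap = 2` also breaks it (two slots is
  the natural cadence of same-side frames). The printed "0.9 s at 3 Hz"
  figure is internally inconsistent with alternating-side capture; we
  adopt the constant-frames reading (`min_frames = 3`) and expose it as a
  parameter.
* **trophallaxis_count** — food-exchange events per pair. The first
  classification stage is a logistic regression on three geometric
  features of a candidate pair: thorax distance, head distance (head =
  thorax + 3.19 mm along the body axis), and relative orientation (dot
  product of unit heading vectors). Only pairs with thorax distance in the
  0.731–1.204 cm gate are scored. The original second stage is a
  convolutional network whose architecture is not specified; `netage`
  keeps a pluggable scorer interface, defaulting to the stage-1
  probability.
* **distance_gaussian**, **distance_max_minus** — daily mean pairwise
  distance d over frames where both bees were visible, transformed with a
  Gaussian similarity exp(−d²/2γ²), γ = max(D)/4, and with max(D) − d.
  The source prints the Gaussian formula without the exponential; exp(·)
  is the only reading that yields a similarity and is adopted. Note that
  after the rank transform both distance modes carry identical
  information (both are monotone in d), which makes the pooled factor
  matrix rank-deficient; the CCA implementation tolerates this (below).
* **effect_mean_pos/neg**, **effect_cum_pos/neg** — directed
  movement-effect networks. For each proximity event with duration ≤ 60 s
  and at least 5 s since the pair's previous event, the change in a focal
  bee's mean speed (and in cumulative distance) between the 30 s windows
  before and after the event is recorded. Positive changes accumulate in
  the `*_pos` matrices, magnitudes of negative changes in `*_neg`, so all
  edge weights stay nonnegative. Multiple same-pair records in a day are
  **summed** — the source states only that the networks are "based on"
  the changes; summing preserves count information consistently with the
  count modes.

Every matrix is rank-transformed: off-diagonal affinities become average
ranks rescaled affinely so the minimum maps to 0 and the maximum to 1.
Ties share ranks; symmetric modes are ranked over unordered pairs so
symmetry survives; zeros (never-interacting pairs) participate as the
lowest tie, because the whole matrix, not its support, is ranked. A
constant matrix maps to 0.5 (no order to assert).

## 2. Embeddings and factors

Symmetric modes are embedded with Laplacian eigenmaps: eigenvectors of
D^(−1/2) A D^(−1/2), skipping the trivial leading vector, keeping the
next 8. Directed modes use the SVD of the row/column-degree-normalized
matrix, giving separate row and column coordinate sets. A uniform
ε = 1e−8 is added to all off-diagonal affinities so the graph is
connected and every alive bee receives coordinates — the alternative
(dropping small components) was rejected because the CCA stage needs
complete rows.

Numerical conventions: dense symmetric eigendecompositions and SVDs
(LAPACK), deterministic; each eigenvector's sign is fixed so its
largest-magnitude entry is positive, with the row/column singular vectors
of a directed mode flipped jointly. Across days, each dimension is
sign-aligned by chaining: day *t* flips when its Spearman correlation
with the aligned day *t* − 1 over shared bees is negative (fewer than two
shared bees: keep the sign, warn). Alignment runs **per embedding set
before concatenation** — whether the original aligned before or after
concatenation is unstated; per-set-before is the only order that is
well-defined when mode inventories change. Eigenvalue crossings between
days can still permute dimensions; like the original, we do not attempt
dimension matching, and document it as a known limitation.

The daily factor vector concatenates all sets in a fixed mode order:
4 symmetric + 4 directed × 2 = 12 sets × 8 dimensions = 96 columns.

## 3. Network age

Factors pooled over all (bee, day) rows are z-scored per column
(zero-variance columns are dropped from the fit and contribute nothing at
projection time; scales across modes are incommensurate after
concatenation, so standardization is required). Two-view CCA against the
4-dimensional task descriptor yields the projection; the first of k = 3
canonical directions is network age. The CCA is computed by SVD
whitening, which handles the rank-deficient factor matrix exactly (null
directions get zero weight); on full-rank inputs it agrees with
`stats::cancor` to 1e−8 (tested).

Per day and dimension, robust scaling maps the 5th percentile to 0 and
the 95th to 40; percentiles use linear interpolation between order
statistics (R quantile type 7) — the source names no definition, so this
one is pinned and tested (a 10,000-value continuous sample leaves exactly
90% of values inside [0, 40]). A degenerate day (all values equal) maps
to the midpoint 20 with a warning. Directionality is then enforced: if
the mean biological age below the pooled 5th percentile exceeds that
above the 95th, the first raw dimension is negated and re-scaled
(flip-then-rescale; the original's order is unstated, and this order
keeps the scaled anchors exact). The unsupervised variant replaces CCA
with PCA; the targeted variant replaces the descriptor with any scalar
property (days until death, peak activity time, circadian rhythmicity,
day/night velocity).

## 4. Lifetime changepoint model

A bee is alive on days [e, e + l). The daily observation is the indicator
that the bee's detection count — normalized by its maximum daily count —
reaches a threshold t; while alive the indicator is Bernoulli(p), after
death Bernoulli(1 − p). The after-death form is implied but not written
in the source; the symmetric 1 − p form is adopted and documented.
Priors: l ~ Normal(35, 50) truncated to l > 0, where 50 is read as the
standard deviation (the "weakly informative" scale; variance 50 would be
strongly informative); p ~ Beta(5, 1).

The threshold prior deserves a note. The source prints "Beta(25, 1)" for
t, which as (shape1 = 25, shape2 = 1) concentrates t near 1. A threshold
near the bee's *maximum* count classifies nearly every day — alive or
dead — as below threshold, and exact enumeration shows the posterior then
prefers degenerate explanations (death on day one, or an inverted p).
The stated rationale — dead bees have very few detections, so the
threshold only needs to clear the false-positive floor — requires t to be
*small*. `netage` therefore defaults to t ~ Beta(1, 25) (mean ≈ 0.04),
the reading consistent with the model's purpose and with the data regime
of ~10⁵ true detections against a handful of false positives per day.
The shapes are configurable in `lifetime_config()`.

Two backends share the day-resolution convention (continuous l in
(k − 1, k] keeps the same days alive as integer l = k):

* **grid** (default): exact enumeration over integer l, with p integrated
  analytically under its Beta prior and t integrated exactly over the
  segments of (0, 1] on which the indicators are constant. Deterministic.
* **mcmc**: Metropolis–Hastings with 2000 tuning and 1000 kept draws,
  mixing a local random-walk kernel with an independence kernel that
  redraws (l, t) jointly from their priors. The joint redraw matters:
  the changepoint mode and the censored "alive past the window" tail
  live in different threshold regions, and a chain moving one coordinate
  at a time cannot cross between them. At the default 1000-sample budget,
  bees with genuinely bimodal posteriors (late deaths leaving few
  zero-count days) still mix slowly; the exact grid is the reference.

The identifiability of death dates hinges on the false-positive floor
being sparse: days with zero detections are what distinguish "dead with
occasional misdecodings" from "alive but rarely seen". With a floor of a
couple of spurious detections per day — the realistic regime — recovery
on 100 simulated bees is within ±1 day for well over 90% of deaths inside
the observation window (computed by the test suite and the acceptance
script).

Id-level filtering uses Otsu's method on the strongly bimodal per-id
total-count distribution, searching all midpoints between consecutive
sorted unique values (equivalent to exhaustive between-class-variance
maximization; tested against brute force), plus a confidence floor and an
implausibility rule (no detections before an id's introduction day).

## 5. Behavioral metrics

The task descriptor samples at most one detection with confidence > 0.9
per bee per minute — the highest-confidence detection in the minute (the
original's within-minute rule is unstated; highest-confidence is
deterministic) — counts point-in-polygon membership in the four annotated
areas, and normalizes to 1. Samples outside every area are ignored.
Point-in-polygon uses the even-odd rule with boundary points counted
inside (cross-checked against `mgcv::in.out` away from boundaries);
overlapping annotations resolve by the priority exit > dance_floor >
brood > honey, configurable.

Circadian rhythmicity fits a single fixed-frequency sine
a·sin(ωt) + b·cos(ωt) + c, ω = 2π/24 h, to the velocities of a 3-day
window; the power P = 1 − SSE_sine/SSE_constant lies in [0, 1] because
the sine model nests the constant one, and is invariant to positive
affine transformations of velocity. Velocities divide consecutive-
detection displacements by elapsed time and are median-filtered with
kernel 3 (endpoints use shrunken windows). Day/night velocities average
09:00–18:00 and 21:00–06:00 UTC. A Lomb–Scargle periodogram is not
required: the fixed-frequency fit is the canonical implementation.

## 6. Evaluation machinery

Task models regress the descriptor on a feature (network age variants,
biological age): jointly with a softmax link and multinomial likelihood
(rows weighted by their sample counts, since descriptor rows are
fractions), per area with a sigmoid/binomial pair, or with identity/
Gaussian for scalar targets. Optimization is deterministic BFGS with
analytic gradients from zero initialization (the nonlinear variant — one
hidden layer of width 8 with tanh — trains full-batch from a fixed seed
with a 1e−6 ridge for identifiability). McFadden's pseudo R² is
1 − ℓ₁/ℓ₀ on log-likelihoods — the only reading that lands in the
reported range. The likelihood-ratio test uses LR = 2(ℓ₁ − ℓ₀) against a
χ² with 4 (task model) or 1 (scalar) degrees of freedom.

Model comparison draws 128 bootstrap replicates of the pooled (bee, day)
rows, refits both models per replicate (warm-started at the full-data
optimum), and reports the percentile 95% CI of the score difference; a
per-bee block bootstrap is available for dependence-aware inference.

Future prediction fixes 12-day training windows: the CCA map and the task
model are fitted on training days only; evaluation happens 1–11 days
after the window on per-day factors (which never mix days, so no
information leaks — asserted structurally). The persistence null carries
the model's prediction for the last training day forward; a paired
binomial test compares per-row squared errors.

Repeatability is R = Var_p/(Var_i + Var_p) with an age-matched control
group; the control age span is not quantified in the source and defaults
to ±1 day, configurable. Trajectory clustering inter/extrapolates each
bee's daily series linearly (ends extrapolate from the two nearest
observations), then applies Ward's method (`ward.D2` on Euclidean
distances) cut at k = 3. The per-day mode split runs 2-means with
deterministic initialization at the day's quartiles, pooled across
cohorts; a separation ratio is reported so unimodal days can be flagged.

## 7. The synthetic colony

The generator exists to give every stage a recoverable target. It
emulates: an age-structured colony (default 200 bees in five cohorts,
25 recorded days) with heterogeneous development — cluster probabilities
0.35/0.35/0.30 for early/late/no transition, logistic role curves
ρ(age) with midpoints ~11 and ~21 days (motivated by the developmental
split observed in real cohorts) and steepness 1.5 days; truncated-normal
lifespans (mean 35, sd 15, ≥ 1 day); task mixtures interpolating between
a brood-concentrated nurse profile and a dance-floor-centred forager
profile; four disjoint rectangular nest areas on a 360 × 260 mm comb;
detections in bursts of consecutive same-side frames with a
24-h-sinusoidal speed modulation for forager-like bees (ρ > 0.5) peaking
at 13:00 UTC; interaction counts Poisson-distributed around a Gaussian
role-similarity kernel (rate 25/day at identical roles, bandwidth 0.3);
directed movement effects whose mean is proportional to the partner's
role excess; and detection counts that collapse to a sparse
false-positive floor (2/day, uniform positions, low confidences) outside
[e, d).

It does **not** emulate: physical bee motion or collisions, comb cells or
pheromones, true contact geometry (affinities are drawn from the kernel,
not derived from simulated trajectories' proximity), observation gaps
from foraging trips, camera homography, or cross-side visibility.
Consequently, passing tests show that the pipeline recovers planted
structure of the kind the method assumes — role-similarity-driven
interactions, task-coupled space use, monotone development — not that it
would survive every pathology of real tracking data. Role trajectories
are monotone by construction; reversals (rare in the real colony) are not
generated.

Scale choices, made once: 240 bursts × 3 frames per bee-day keep a full
default colony around 2.4 million detections; the affinity-based pipeline
(which is what the recovery and comparison analyses use) runs in seconds
because it skips detection-level network construction. The lifetime
analyses use 100 bees over 90 days with a 100/day alive detection mean,
so that most deaths fall well inside the window — identifiability of the
posterior mean degrades near the censoring boundary, which is a property
of the model, not of the implementation. The robustness property for
sparse tracking is exercised at a 25% bee subsample: at 200 bees, the 5%
regime of a 2000-bee colony would leave 10 bees, fewer than the 8
embedding dimensions allow.

## 8. Known limitations

* Dimension permutation across days (eigenvalue crossings) is undetected;
  only signs are aligned.
* The two distance modes are redundant after rank transformation; they
  are kept for fidelity to the mode inventory.
* The posterior-mean death date inherits mass from the censored tail for
  bees dying close to the end of the recording; the MAP is typically
  correct but the mean can exceed it by days. Longer recordings shrink
  the tail exponentially with the number of observed zero-count days.
* Network age is colony-internal: embeddings of disjoint colonies live in
  unrelated coordinate systems, and no cross-colony extension is
  attempted.
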