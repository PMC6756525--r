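---
title: "Inferring social diving rules in seabird foraging rafts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring social diving rules in seabird foraging rafts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftdives)
```

## The model

Surface-foraging seabirds such as shags form "rafts": polarized flocks of
up to a few hundred birds swimming along the surface and diving together.
`raftdives` studies one question about these rafts: do birds time their
dives on private information alone, or do they respond to the dives of
conspecifics they can see?

The core model is a two-rate Bernoulli hazard on a 0.5 s grid. Bird $i$'s
state in interval $t$ is $X_t \in \{0, 1\}$ (a dive begins in the
interval or not), with

$$P(X_t = 1) = \begin{cases}
 p_1 & \text{a conspecific dive qualifies as a cue} \\
 p_0 & \text{otherwise,}
\end{cases}$$

where a conspecific dive qualifies if it happened within the previous
$T$ seconds (`lag`), at a distance of less than $D$ body lengths
(`dist`), and within the focal bird's visual arc $\theta$ (`arc`, the
total angular sector centred on its heading: the absolute bearing must
not exceed $\theta/2$). Conspecific dives keep their exact continuous
times; only the focal's dive indicator is discretized. Probabilities are
parameterized per second and converted to the interval scale by the
complementary-hazard form $q = 1 - (1 - p)^{0.5}$, so the same $p$ means
the same thing at any discretization.

All five parameters get independent uniform priors ($T$ on 0.5–2 s, $D$
on 0–100 BL, $\theta$ on 0–360°, $p_0, p_1$ on [0, 1]) and are sampled
by MCMC. Two reduced variants support the model comparison: `noangle`
fixes $\theta = 360°$ (birds react to dives anywhere around them, as
they would if everyone responded to the same external stimulus) and
`null` keeps only $p_0$ (no social effect at all). Variants are ranked
by WAIC, $-2(\mathrm{lppd} - p_\mathrm{WAIC})$, computed from the
pointwise posterior log-likelihoods.

## Why a random-walk sampler

The likelihood is discontinuous in $T$, $D$ and $\theta$: moving a
boundary past any single cue flips a record's label and the likelihood
jumps. Gradient-based samplers are therefore inappropriate;
`run_mcmc()` uses component-wise random-walk Metropolis with reflecting
Gaussian proposals at the prior bounds. Proposal scales adapt toward a
44% acceptance rate during burn-in only and are frozen afterwards, so
the kept draws come from a fixed kernel. Because the likelihood between
cue boundaries is piecewise constant in the zone parameters, the arc
component in particular shows mild meta-stability — the chain sits on
plateaus separated by small jumps of a few degrees. This is expected
behaviour, visible as a slightly lumpy arc trace, and is why the
recovery checks allow the arc estimate a wider band (25°) than the
other parameters.

Rate updates ($p_0$, $p_1$) reuse the cached social/dive counts, so they
cost O(1); only zone proposals rescan the candidate-cue table, in a
small C++ kernel. Candidate cues are precomputed once per dataset at the
prior upper bounds (2 s, 100 BL), which makes every admissible proposal
evaluable without touching the raw trajectories — the accelerated path
is checked against an exhaustive all-dives scan in the test suite.
WAIC is accumulated streaming over posterior draws (each draw relabels
the records and contributes one of four Bernoulli log-masses per
record), so the full pointwise matrix is never materialized.

## The synthetic-raft generator

No field data ship with the package, so everything is exercised on
synthetic rafts built by `simulate_raft()`. Its defaults are the study
conditions the package is calibrated to: rafts of ~103 birds (range
50–156 in `recovery_config()`), 60 s clips, 25 frames per second, mean
speed 1.1 BL/s, initial placement targeting a mean nearest-neighbour
distance of 9.3 BL, and dive behaviour generated with the empirically
inferred parameter means ($p_0 = 0.0634$/s, $p_1 = 0.1484$/s,
$T = 1.67$ s, $D = 70.28$ BL, $\theta = 216.06°$).

Two design points matter:

* **Dive trials run on the model's own 0.5 s decision grid.** At each
  interval start the social state of every surfaced bird is evaluated
  from the exact times and locations of earlier dives; the bird dives
  within the interval with probability $1-(1-p)^{0.5}$ and the exact
  instant is drawn uniformly within it. Movement still integrates at
  the frame step (0.04 s). Drawing trials per frame instead would make
  the generating process differ from the inference target (states can
  flip mid-interval), and any recovery bias would then be an artifact
  of the surrogate generator rather than a property of the method. With
  the decision-grid convention, `discretize_dives()` + `is_social()`
  reproduce the generator's internal labels exactly, which the test
  suite asserts.
* **The movement rule is surrogate structure.** Birds steer toward a
  shared travel direction, weakly toward the raft centroid, and toward
  the nearest neighbour in their front half-plane, with Gaussian
  heading noise. That rule set is the simplest one that reproduces the
  qualitative spatial structure of real rafts — polarized motion with
  high circular variance, and higher neighbour density directly ahead
  and behind the focal than to its sides. No claim is made that real
  birds move this way; the walk only has to carry the dive process.

Dived birds do not resurface by default (resurfacing birds can never be
linked to their pre-dive identity, so they are new birds for every
analysis). A depleting raft is the right object for parameter recovery,
but it concentrates observations in the brief cascade phase in which
nearly every bird has an active cue, and marginal front/back cue effects
saturate. The spatial analyses therefore use `respawn = TRUE` (each dive
schedules a fresh bird after an exponential delay, 1/rate = 25 s by
default in the scripts), which emulates the sustained surface population
of real footage. The initial-placement density is calibrated so the
*initial* mean NND matches the 9.3 BL target; the whole-clip pooled NND
drifts upward as the raft thins, which is visible in
`summary_stats()` and expected.

What the generator deliberately does not emulate: underwater movement,
prey fields, kleptoparasites, lighting or sea-state variation, birds
entering and leaving the camera frame mid-clip, and the manual
track/dive corrections applied to real footage. Passing tests therefore
demonstrate that the pipeline recovers the truth of this generative
process at the study's data scale — not that every videography
complication is handled.

## The rendering and tracking stage

`render_frames()` projects a raft through a pinhole camera model
(default: 31.6 m elevation, bottom-edge inclination 79.46° from
vertical, 1920×1080 at 25 fps) onto grayscale frames: one bright
elliptical blob per surfaced bird, foreshortened by the local pixel
scales, with an optional flicker/Gaussian noise model. A dive renders as
a splash: the blob swells for 0.3 s and shrinks to nothing within 0.8 s.

`track_frames()` then runs the recovery chain: temporal frame averaging
(default window 6 frames, the typical flicker-suppression setting),
thresholded connected-component blob detection with an area filter
(defaults 8–60 px around the ~20 px bird size), inverse projection onto
the sea surface, constant-velocity Kalman (LQE) prediction with auction
assignment of detections to tracks (pairings beyond a 2 m gate are
forbidden; tracks unmatched for over 0.5 s close), a 0.2–2.5 BL/s mean
speed filter, and dive detection from track endings.

Numerical choices worth knowing:

* **Assignment.** The auction algorithm with epsilon scaling solves the
  frame-wise minimum-cost matching exactly (to within $n\varepsilon$,
  $\varepsilon = 10^{-9}$); the tests compare it against brute-force
  enumeration for up to six detections. Unmatched options enter the
  square cost matrix as gate-priced dummy slots.
* **Dive criteria.** A track must end inside the frame's bounding box
  (10 px margin — edge-enders simply left the view) and its final 2 s
  of area must rise at least 30% above baseline and then fall at least
  60% from the peak *or* vanish within 0.6 s of the peak. The vanish
  clause exists because a shrinking splash drops below the detection
  floor before its full decline can be observed; without it, recall
  degrades exactly for the cleanest dives. The paper-scale thresholds
  are config-exposed because real footage varies. A secondary
  sudden-turn criterion exists but is off by default.
* **Body-length scale.** By default the median projected blob major
  axis sets the BL-to-metre factor; whenever the true scale is known it
  should be overridden. Track breakages around blob mergers (birds
  passing within about a body length) are the dominant residual error
  source, mirroring the cases that needed manual correction in real
  footage.

## Spatial statistics

All focal-frame statistics rotate offsets so the focal's heading points
"front" (+y) and bin them on a 40 BL half-width grid of 2 BL cells (the
extent and cell size are declared choices; nothing in the source data
fixes them). Density maps are normalized so the densest cell is exactly
1. Heading maps report the circular mean and the circular variance
$1-\bar R$ per cell; empty cells are missing, not zero. The
fraction-followed map bins, for every (focal, conspecific-dive) pair at
the dive's moment, whether the focal itself dived within the next 2 s.
Its front-vs-back bias statistic is computed among dives within the
grid extent — more distant dives cannot be cues and only dilute it.

The randomization null reassigns each dive time to a random bird
surfaced at that moment (1000 permutations), preserving all positions
and orientations; everything that does not depend on the assignment is
precomputed, so the null costs a few vectorized passes per permutation.
The wave diagnostic emits, for each ordered dive pair within 30 s, the
time difference and the along-heading offset, and scores the excess of
behind-offset far pairs (time difference beyond the 2 s social lag). A
sweeping-front generator (`simulate_wave_raft()`) produces strongly
positive scores; socially generated data do not.

## Problem sizes and reproducibility

The shipped experiments use: 26 rafts × ~103 birds × 60 s for parameter
recovery (≈40k records, ≈500k candidate cues; full-model MCMC with 5000
burn-in + 20000 draws runs in a few minutes), 26 sustained rafts for the
spatial suite with the full 1000-permutation null, and three rendered
20 s scenes of 30-bird rafts at 960×540 for the tracking round trip.
Every stage takes an explicit seed and is bit-reproducible under it;
`run_recovery_experiment()` records config, derived seeds, timings and
outputs in a manifest sufficient to re-run the experiment.

## Known limitations

* The movement model is a surrogate; spatial statistics on synthetic
  data inherit its simplifications (no leading-edge dynamics, no
  environmental gradients).
* Dive rates at the inferred means depleting a non-respawning raft
  within tens of seconds is a model property, not a bug, but it means
  whole-clip summaries (NND, speed spread) are not stationary.
* The tracker does not attempt underwater continuity or re-identification
  of resurfacing birds, and close-pass blob mergers can break tracks.
* The per-second vs per-interval probability convention is declared
  (complementary hazard), not inferred; all components share it, so
  estimates are internally consistent.
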