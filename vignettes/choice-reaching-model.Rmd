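---
title: "A dynamic neural field model of choice reaching under perceptual grouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic neural field model of choice reaching under perceptual grouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachfield)
```

## The task and the model

In the colour-oddity choice reaching task (CRT) a participant sees three
items, reaches for the one with the odd colour, and the reach itself is
the dependent measure: *initiation latency* (IL, when the hand starts
moving) and *maximum deviation* (MD, how far the trajectory bows away
from the straight line to the target). Item *size* varies but is never
task-relevant, and the sizes of the two distractors manipulate two
Gestalt factors: similarity grouping (can the distractors be grouped as
"same"?) and proximity grouping (does a large item group with its large
neighbour?). The empirical signature is that IL falls as distractor size
grows (dd > Dd > DD), while MD peaks for mixed distractor pairs (Dd),
worst of all when a large target sits in the display with a large
distractor.

`reachfield` simulates this task end to end as a closed-loop dynamic
neural field (DNF) system:

1. **Stimulus generation** — the 24 condition codes (target position ×
   target size × distractor arrangement) rendered as 30 × 30 RGB images
   of filled discs.
2. **Visual front end** — binarise, label 4-connected components,
   identify the odd colour, compare sizes, and assign each item a tuned
   *saliency level* plus a per-condition *movement-onset scaling
   factor* indexed by the distractor pair.
3. **Target selection** — three recurrent competition nodes (one per
   item) receive the saliency levels and run a winner-takes-all (WTA)
   race; their outputs weight Gaussian *spatial location maps* that feed
   a 2-D *target location field*.
4. **Motor stage** — the target field output is cross-correlated with a
   Gaussian *hand map* to form a *hand–target displacement field*; a
   two-layer *velocity field* turns the displacement blob into a motor
   command; the supra-threshold activation centroid moves a planar end
   effector, which immediately feeds back into the displacement
   computation (closed loop).
5. **Analysis** — IL from a degree-10 polynomial fit of the speed
   series (first sustained crossing of 10% of the run-global maximum
   speed), MD as the largest perpendicular distance to the start→target
   line, a bell-shape (unimodality) test, condition summaries, and a
   normalised comparison against user-supplied reference profiles.

Because selection and movement run *concurrently*, unresolved
competition leaks into the early movement: the hand first heads toward
a blend of all item locations and is corrected as the competition
resolves. That leakage is what curves the trajectories.

## Node and field dynamics

Every unit obeys leaky-integrator dynamics with a logistic output
$f(u) = 1/(1 + e^{-\beta(u - u_0)})$, $u_0 = 0$. The competition nodes
follow

$$\tau \dot u_i = -A u_i + B f(u_i) + C I_i + D \textstyle\sum_j f(u_j) + h + \epsilon$$

with $\tau = 20$, $h = -1$, $\beta = 1$, $A = 1$, $B = 7$, $C = 0.7$,
$D = -4$, noise s.d. 0.005. The global sum runs over all nodes
including the node itself; self-excitation is carried separately by
$B$. Linearising around the symmetric state shows the differential mode
is unstable (growth rate $\approx 0.031$ per step) while the common
mode is stable — the network amplifies input differences into a
winner. Two regimes deserve note:

* With the default level table (small target 5.0 > large target 4.8 >
  small distractor 4.6 > large distractor 4.4) the target always wins,
  for all 24 conditions.
* If two inputs both exceed ≈ 4.95 and differ by less than ≈ 0.06 the
  network has a stable two-winner state; `run_wta()` reports such
  stand-offs (and exact ties) rather than breaking them silently. The
  saliency table never enters this regime.

The 2-D fields use the same dynamics with interaction kernels
$w(x) = c\,\mathcal N(0,\sigma)$ per dimension, i.e. a separable
Gaussian of total mass $c$ (the strength constant is applied per
dimension; applying the one-dimensional normalising constant verbatim
to a 2-D kernel would give the velocity field an excitatory kernel of
mass ≈ 41 and drive it into global saturation from rest). Lateral
interaction is local excitation minus surround inhibition plus a global
term $g_{inh}\sum f$. Parameters per field (rows: $\tau$, $h$, $\beta$;
kernels: $c_{exc}$, $\sigma_{exc}$, $c_{inh}$, $\sigma_{inh}$,
$g_{inh}$):

| field | $\tau$ | $h$ | $\beta$ | $c_{exc}$ | $\sigma_{exc}$ | $c_{inh}$ | $\sigma_{inh}$ | $g_{inh}$ |
|---|---|---|---|---|---|---|---|---|
| target location | 20 | −1 | 4 | 3 | 7.5 | 1 | 15 | 0 |
| displacement    | 30 | −5 | 4 | 3 | 5.5 | 0 | — | −0.01 |
| velocity (2 layers) | 30 | −0.2 | 4 | 3 | 5.5 | 1 | 10 | −0.005 |

A weak proprioceptive kernel (c 0.005, σ 1) feeds the hand map into the
displacement and velocity fields. Integration is explicit Euler with
dt = 1; tests compare the competition winner against a dt = 0.1
integration. Kernel convolutions zero-pad at the lattice border;
stimulus geometry keeps item blobs away from the border so nothing of
consequence is clipped.

One property of the target-location kernel matters for the science: at
the 8 px item spacing the *net* lateral interaction is excitatory (the
excitation/inhibition crossover sits near 19 px), so neighbouring item
blobs attract and merge. This is the field-level expression of
proximity grouping.

## How the two grouping effects enter

**Similarity** enters through the saliency table: similar distractors
have equal levels and share the competition load. A consequence of the
node equation — visible in simulation and central to the MD pattern —
is the *persistent survivor*: with mixed distractors (Dd) the weak
large distractor drops out early and stops contributing inhibition, so
the surviving small distractor settles at roughly twice the output of
either distractor in a matched pair (f ≈ 0.22–0.29 vs ≈ 0.13) and holds
it for well over a hundred steps. With a large target the survivor is
strongest and longest-lived of all conditions. That lone persistent
blob keeps pulling the motor command sideways, which is why mixed pairs
curve trajectories most and the large-target mixed cell is worst.

**Proximity** enters twice. Spatially, each item's location map is a
unit-peak Gaussian whose width scales gently with the item's radius
(width $1.5 \cdot (r/2)^{0.14}$ px), so large items cast slightly
larger blobs and the kernel's short-range attraction binds them to
their neighbours. Temporally, the distractor pair sets the
movement-onset scaling factor $s_{prox}$ (defaults 0.125 for dd, 0.1
for Dd/dD, 0.075 for DD), implemented as a hard onset gate: the
velocity-field drive is suppressed for the first
`round(640 * s_prox)` steps of a trial. Larger factors delay movement
onset, raising IL directly; they also shorten the leakage window, so a
sufficiently large factor *reduces* MD — which is exactly why the
coarse factor table (0.35, 0.2, 0) buys a clean IL ordering at the cost
of an inverted dd-vs-DD deviation pattern, while the tuned table keeps
both patterns.

## The motor readout

The displacement field input is the cross-correlation of the
(continuous) hand Gaussian with the thresholded target-field output,
evaluated on a lattice whose centre means "hand on target"; it is
computed separably as two matrix products, which also zero-pads
displacements beyond ±14 px. The first velocity layer receives the
gated displacement activation plus a centre-anchored Gaussian kick
(amplitude 2, σ 3 px, the standard negative-exponent form); the second
layer receives the first layer's excitation/inhibition projection,
scaled by an inter-layer coupling gain of 8 whose DC component is net
inhibitory, so the readout layer rests safely below the movement
threshold and saturates into a clean blob when driven.

The hand moves only while the readout layer's peak output exceeds 0.5.
The command is the offset of the layer's background-corrected
activation centroid from the map centre (activation below the resting
output carries no vote), times gain 0.01 px/step per px of offset,
times a saturating function of the blob mass (half-formed blobs move
the hand slowly — this produces the rising limb of the bell-shaped
speed profile; the decaying offset as the hand closes in produces the
falling limb). Using the background-corrected centroid rather than only
supra-threshold mass lets persistent sub-selection blobs deflect the
command — the leakage pathway. A trial ends when the hand is within
1.5 px of any item centroid, or after 500 steps (reported as
non-convergent, excluded from condition means, counted).

## Calibration choices and their reasons

The parameter tables above are fixed. The remaining constants are
calibration, chosen once on deterministic (noise-off) runs and then
frozen:

* **Stage input gains** (target field 5, displacement 2, velocity 1):
  node outputs and field outputs are bounded by 1, so each projection
  needs a gain for the receiving field to form blobs at all. The
  target-field gain of 5 is chosen so that an early, still-undecided
  node output (f ≈ 0.35) already pushes item blobs above the field's
  knee — the "all items represented before selection" phase — while a
  suppressed matched-pair distractor (f ≈ 0.13) falls back below it,
  letting the persistent Dd survivor (f ≈ 0.22+) stand out.
* **Onset gate scale, 640 steps per unit factor**: the motor cascade
  (three τ = 30 fields in series) crosses the movement threshold about
  40–70 steps into a trial on its own. Gate delays must be of at least
  that order to control movement onset; at this scale the tuned factor
  table gives delays of 48–80 steps and the coarse table 0–224 steps.
* **Motor gain 0.01**: the loop from hand position through three
  fields back to a velocity command has ~60–90 steps of effective lag;
  faster hands orbit the target (a delayed-feedback limit cycle,
  observed directly at gain 0.05). At 0.01, reaches take roughly
  150–400 steps, well inside the 500-step budget.
* **Location-map size exponent 0.14**: at 0 (fixed-width maps) the
  matched small pair out-pulls the mixed pair; at 1 (width ∝ radius)
  two large distractors dominate everything. The small exponent
  balances the two so that the mixed pair — helped by its persistent
  survivor — carries the largest deviation, with margins of order
  0.02–0.1 px. These margins are genuinely small; the pattern is a
  knife-edge property of the model, consistent with the fact that the
  deviation pattern flips under the coarse factor table.
* **IL estimator sustain window (5 steps)**: a degree-10 polynomial
  fitted to a speed series with a long motionless stretch oscillates
  around zero there; requiring the fitted curve to stay above threshold
  for 5 steps after crossing rejects those artefacts while moving a
  genuine crossing by less than the dense-evaluation step.

## The synthetic stimuli, and what the tests do not show

The generator enumerates all 24 codes, renders filled discs (small
radius 2 px, large 3 px) on a black background with pure red/green
item colours, centred on one row at columns 7.5/15.5/23.5 of the 30 ×
30 lattice — symmetric about the centre column, so mirrored condition
codes produce exactly mirrored trials, and spaced so that two adjacent
large discs remain 4-disconnected. Batches contain every code once per
set in seeded shuffled order; 25 sets (600 trials) is the reference
layout. Per-trial seeds derive deterministically from the master seed,
so a run is bit-reproducible from its configuration alone.

The displays emulate the *structure* of the human experiment's stimuli,
not their appearance: real displays have textured backgrounds, larger
canvases, photometric noise, and continuous size variation. The model's
front end is a lookup (classification to a letter code followed by a
table), so passing the round-trip and pattern tests says nothing about
robustness to natural images. Likewise the human reference values exist
only as published figure plots; `compare_reference()` therefore takes a
user-supplied table rather than bundling digitised data, and no test
asserts a quantitative fit to the human curves.

A few conventions: all coordinates are 1-based (row, col) with row
increasing downward, matching R's indexing; the classification rule
falls back to an absolute area split (21 px) when all three items share
one size class, which is what makes the all-large codes recoverable;
the size-comparison tolerance is ±2 px of area.

## Degenerate inputs and numerical edges

Rendering rejects malformed codes, overlapping or touching discs, and
geometry violating the border margin. The front end errors on empty
foregrounds, merged components (item count ≠ 3), and colour patterns
that violate oddity (all same, all distinct). `run_wta()` reports exact
ties and two-winner stand-offs instead of picking arbitrarily.
`initiation_latency()` errors when the fitted speed curve never
sustains the threshold ("no movement detected"); `max_deviation()`
errors on a degenerate start = target line;
min–max normalisation refuses constant condition vectors. Any
non-finite field value aborts the trial with a diagnostic rather than
propagating NaNs.

## Reference experiment scales

Package defaults run the reference layout: 25 sets × 24 displays = 600
trials, noise s.d. 0.005, master seed 1. A 600-trial experiment takes
roughly two to three minutes on one core; the factor-sweep used for the
onset-monotonicity check runs 5 sets per factor value. The deterministic
pattern probes in the vignette and tests use single noise-free trials
per code where that suffices.

## Known limitations

* The displacement lattice equals the display lattice (30 × 30), so
  hand–item offsets beyond ±14 px fall off the map; item geometry and
  the start position keep task-relevant offsets inside, but an
  opposite-side distractor's blob leaves the map late in a reach,
  muting its influence at that stage.
* The deviation pattern's defining margins (mixed pair above both
  matched pairs) are small relative to the between-condition spread and
  depend on the calibration; they hold at the reference conditions and
  seed, not as a large-margin universal property of the dynamics.
* Two distractors only; the architecture has exactly three competition
  nodes. Planar end effector; no joint-space kinematics, no torque
  dynamics.
* Selection history (priming across trials) is out of scope: every
  trial starts from a hard reset of all fields.
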