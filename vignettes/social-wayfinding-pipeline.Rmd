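---
title: "Models and methods behind the social-wayfinding gaze pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the social-wayfinding gaze pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swgaze)
```

`swgaze` analyses locomotion and eye movements from a social-wayfinding
task: a participant crosses a 5 × 6 m virtual waiting room, passing two
perpendicular rows of walking pedestrians, toward an exit gate revealed
2 s into the trial. This vignette documents the models the package
implements, the defaults and why they were chosen, and what the
synthetic-data generator does and does not emulate.

## Coordinates and scene

Right-handed coordinates, y up: x is lateral (midline at 0, positive
toward the right gate), z is depth from the start line (0) to the far
wall (6 m). All positions are in meters, times in seconds. The default
scene places the walker rows at z = 1.4 and 4.7, the gate-indicator sign
at z = 1.7, two standers at z = 3 near the side walls, and the gates and
timer on the far wall. Every object carries an axis-aligned box
collider, which keeps ray tests exact and deterministic.

Two choices were genuinely open and were fixed as follows. The bench
arrangement is only qualitatively constrained (back-to-back pairs at the
room centre forcing a left/right choice), so the default is a
1.2 × 2.4 m block centred at (0, 3.05) with sitter slots extending 0.3 m
beyond each long side — the slots stand for the space taken by sitters'
extended legs, and path-shape analyses use the matching bench zone
z ∈ [2.0, 4.1]. Second, the gate colliders are *openings*: the
participant is expected to walk into them, so collision guarantees apply
to furniture and people, not gates or walls.

## Synthetic data

The generator's purpose is to make every pipeline stage testable with
known ground truth. It is a first-class module, not a fixture.

**Walkers.** Each row is an infinite single-file train: agents at fixed
z, equal 2.5 m spacing, constant 1.3 m/s, entering at one side wall and
leaving at the other, with the row fully populated from t = 0. Tracks
are exact linear kinematics, so speed and spacing are recoverable from
the logs to machine precision. A per-row phase offset slides the whole
train along its travel direction; the trial assembler uses it to place a
gap at the participant's crossing.

**Participant.** The head trajectory is a closed-form construction. The
participant stands still until the cue (2 s) plus a reaction delay
(default 0.4 s), then moves with the depth-speed law

v(z) = v₀ · (1 − d · exp(−(z − c)² / 2w²)),

a Gaussian slowdown of fractional depth `d` centred between the rows
(c = 3.05 m, w = 0.6 m). Defaults v₀ = 0.9 m/s, d = 0.45 reproduce
realistic trial durations near 10 s with the mid-room hesitation seen in
real speed profiles. The lateral path is a smoothstep swerve to a
passing offset (default 1.0 m, clearing the sitter slots) held through
the bench zone, then a blend to the gate. With probability
`hook_probability` the trial is *hooked*: the path holds the wrong side
and crosses the midline only after the bench zone. Crossing position
within each walker gap is drawn as 0.5 + bias + noise (clamped to
[0.1, 0.9]); the row phase is then solved so that the rear-facing walker
sits exactly that fraction of a gap behind the crossing point. This
makes the gap-fraction knob exactly recoverable by the analysis.

**Gaze.** Gaze is a sequence of episodes: fixations on static objects
and smooth pursuit of walkers, sampled from a per-phase target pool.
Transitions are saccades with a minimum-jerk time course and an
amplitude-scaled duration (20 ms + 2 ms/deg), optionally followed by a
damped post-saccadic oscillation (50 ms, 15 Hz, 1° amplitude) — chosen
to give the classifier realistic velocity signatures without claiming
physiological fidelity. Pursuit ends no later than the moment its walker
leaves the room. Two error processes scatter the gaze point: a slow
Ornstein–Uhlenbeck drift (0.5° s.d., 0.8 s time constant — tracker
drift and fixational wander are slow, which is why pre-smoothing the
velocity signal buys little) and a per-episode angular landing offset
(1° s.d.). Both displace the point laterally and vertically at the
target's distance, never in depth, so gaze lands scattered across an
object's surface rather than behind it. Both eyes converge exactly on
the (noisy) point from origins ± half an inter-pupillary distance
(63 mm), so vergence reconstruction is always well posed; frame validity
is the only masking mechanism.

**Pupil.** The signal is baseline (3.5 mm) + a fixed low-frequency
oscillation (0.15 mm at 0.8 Hz) + load-driven high-frequency activity +
white noise (0.01 mm). High-frequency activity is *bursty*: time is cut
into 0.6-s slots and cognitive load sets how many slots carry a
Gaussian-windowed oscillation packet (0.10 mm peak, 2.5–5 Hz). Because
packets occupy disjoint slots, band power is proportional to the packet
count — doubling load doubles high-band power — and the pupillary index
below responds monotonically, which a stationary load-scaled sinusoid
would not produce (scaling every coefficient equally leaves
maxima counts unchanged).

**What the generator does not emulate.** Blinks and tracking dropouts
(beyond a validity flag), eye-in-head vs head-in-world decomposition
(headset orientation is not modelled), gait oscillation of the head,
agent appearance, and any adaptive coupling between gaze and steering.
Passing tests therefore demonstrates that the *pipeline* recovers what
the generator encodes, not that real behaviour looks like the generator.

## Gaze geometry

The vergence point is the midpoint of the shortest segment between the
two eye rays, restricted to non-negative ray parameters (when the free
optimum lies behind an eye, both boundary edges are evaluated and the
closer one taken). The segment length is kept as a quality measure.
Near-parallel rays (cross-product norm < 1e−9) have no usable
intersection and the frame degrades to the collider fallback.

Attribution is two-stage: the nearest object whose collider contains or
lies within `snap_radius` (default 0.1 m, sized to absorb vergence noise
at 1–4 m viewing distance) of the vergence point wins, ties broken
toward the smaller collider; otherwise the cyclopean ray (mean origin,
renormalized mean direction) is cast and the nearest positive-parameter
box hit wins. The published approach used the collider intersections as
a sanity check without defining a precedence; the fallback order here is
a package choice.

For entropy analysis gaze points are discretized into a 6 × 12 × 3 grid
over the room footprint; the height span 0–2.5 m is a package default
since only the bin counts are prescribed. Out-of-extent points clamp to
boundary bins; invalid frames propagate as missing states.

## Event classification

Angular kinematics come from central differences on unwrapped
azimuth/elevation of the cyclopean direction (great-circle rates). The
I-VT classifier thresholds a Savitzky–Golay velocity estimate (window
11 frames ≈ 137 ms at 80 Hz, order 3) at 100 deg/s — higher than
desktop norms because head-free VR gaze is noisier — and merges
sub-60-ms fixations into the surrounding saccade.

The four-state HMM uses diagonal-Gaussian emissions on log(1 + speed)
and log(1 + |acceleration|) from the *raw* central-difference
kinematics: the drift noise is slow, so pre-smoothing mostly blurs
saccade boundaries without suppressing it. Emissions are initialized
from a physiological threshold partition (saccade > 150 deg/s;
PSO > 1500 deg/s²; pursuit > 8 deg/s; fixation otherwise) with each
group's empirical moments, and EM runs as a MAP procedure with a
conjugate prior of 1000 pseudo-frames anchoring each state's mean at its
initial signature. The anchoring matters: unconstrained EM on these
features drifts toward a likelihood-optimal clustering that merges slow
pursuit with fixation and splits wide classes, because the true classes
are not Gaussian. The transition prior is sticky-diagonal, and the PSO
state is structurally reachable only from the saccade state (its
defining property). After Viterbi decoding, states are relabelled by
mean speed (slowest = fixation, fastest = saccade), the faster-middle
state with the higher mean acceleration becoming PSO and the other
pursuit. Ties in the Viterbi backtrack resolve to the first index, so
decoding is deterministic.

Classifier benchmarks run on streams from a *stationary* observer
watching the scene. During locomotion a fixation on a static object
rotates in world coordinates at walker-like angular speeds — with the
headset's orientation unrecorded, eye-in-head angles are unavailable and
this ambiguity is irreducible, for any classifier. Stationary streams
are where frame-label accuracy is a meaningful measure of the classifier
itself; locomotion trials are still classified, with that caveat.

## Trial segmentation

Phase labels follow time and depth: initial preparation while t < 2 s
and z < 1.4; approaching first row until z reaches 1.4 (the boundary
frame belongs to the later phase, matching the strict inequality on the
earlier one); approaching second row until z reaches 4.7; approaching
gate beyond. Labelling is monotone — a brief backward dip in z never
re-opens a closed phase — which also settles what happens if a
participant crosses row 1 before the cue: the later phase wins. Each
phase splits into four equal-duration quarters, giving 16 mini-phases.

Arrival is the first entry of the head's (x, z) into a gate's arrival
box (gate width × 0.3 m deep at the far wall). A foil-box visit shorter
than 0.25 s on the way to the target counts as a pass-through rather
than an arrival, because hooked paths may skirt the foil gate; the
published arrival criterion is unstated and this rule is a
reconstruction. Success requires target arrival within deadline + 1 s.
Filtering is two-stage in the published order: durations > 16 s are
removed before any statistics, wrong-gate trials after the performance
statistics but before gaze analyses; hooked trials are excluded only
from path-shape analyses, as a per-analysis mask rather than a drop.

A path is hooked when its mean x over the bench zone lies opposite the
target-gate side (a mean of exactly zero counts as the target side) and
it crosses the midline after the bench zone — a reconstruction of a
criterion the source material only illustrates.

## Metrics

**Allocation.** The phase-by-object attention map follows the task's
goal hierarchy; the timer appears as both a future-phase and an
information target in one phase, resolved as task-related everywhere
(information sources take precedence). Unlisted kinds and unattributed
frames are miscellaneous. Proportions are over attributed frames per
segment and sum to one.

**GTE.** Within each 80-frame rolling window (stride 1; a tiling stride
is equally defensible but rolling preserves the per-phase averaging),
first-order transition probabilities are estimated among the states
*observed in that window*, and the conditional entropy is normalized by
log₂ of that observed-state count — normalizing by all 216 states would
keep short windows far from 1 by construction. Windows with fewer than
two distinct states are missing, never zero.

**K coefficient.** Pairs are fixations immediately followed by a
saccade; fixations followed by pursuit or PSO are unpaired and excluded.
Standardization is per trial — per-phase scopes would leave single-event
phases undefined — so the grand mean of K within a trial is zero by
construction, and per-phase means are contrasts around that.

**Gap crossing.** Measured along the row's travel axis (the row is a
line at fixed z) at the first frame the participant reaches the row:
distance to the walker just passed (rear-facing) and to the oncoming
walker (front-facing), summarized as d_rear / (d_rear + d_front).

**LHIPA.** The pupil series (gaps ≤ 0.2 s linearly interpolated, longer
gaps rejecting the window) is decomposed with a periodized sym16
pyramid transform, implemented in the package. The high band is the
detail level covering ≈ 2.5–5 Hz at the stream's rate (level 4 at
80 Hz), the low band two levels deeper (≈ 0.625–1.25 Hz). In each band,
modulus maxima exceeding a Donoho universal threshold
σ̂ √(2 ln n) — with σ̂ the MAD-based noise scale from the finest detail
level — are counted, and the index is the low-band rate divided by the
high-band rate. Cognitive load drives high-frequency pupil activity, so
the index falls as load rises. The cited construction divides low-band
by high-band coefficients before maxima detection; the rate-ratio form
used here keeps the same low/high semantics while making the
load-monotonicity explicit and testable, and is recorded as a package
design choice. Constant windows (no maxima) are flagged degenerate.

**Density maps.** 2D (x, z) histograms at 0.1 m bins smoothed with a
0.3 m s.d. Gaussian kernel and normalized to unit mass; the kernel is
prescribed, the bin size is a package default.

## Numerical and testing choices

All randomness flows through explicit integer seeds; sub-seeds for the
participant, gaze, and pupil generators derive from the trial seed, and
session runs derive per-trial seeds from the session seed, so every
artifact is a pure function of (configuration, seed). The test suite
verifies the closed-form geometry against brute-force grid minimization,
the binning against explicit edge search, entropy against hand-computed
empirical-matrix values, and the wavelet transform against frozen
reference coefficients. Parameter-recovery suites use seeded cohorts of
100 trajectories (gap fraction, hooked prevalence), 25–30 s stationary
gaze streams at three noise levels (HMM accuracy, averaged over two
streams per level), 60 s pupil records over four load levels (index
monotonicity), and an eight-trial full-pipeline cohort for the
qualitative phase-allocation pattern; these sizes give stable statistics
for the assertions made while keeping the default suite fast.

## Known limitations

Frame-level accuracy of the HMM during locomotion is bounded by the
world-referenced ambiguity described above. The vergence quality measure
is not propagated into a formal confidence weighting of attribution.
The exclusion ledger tracks counts, not per-participant structure, since
the package operates at session granularity. And the generator's
realism limits — listed in the synthetic-data section — bound what any
green test implies about recorded human data.
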