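---
title: "ethotracer: models, rules and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ethotracer: models, rules and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ethotracer` reimplements the computational core of a stereo-vision
behavioral monitor for individually caged flies: a deterministic
rule-based classifier that turns 3D trajectories into six-behavior
ethograms, the acquisition arithmetic around it (5 Hz, 60 s bouts, nine
cages round-robin), a ground-truth simulator used to validate the
classifier and the summaries, and the lifetime analytics built on top.
This vignette records the models, the tunable parameters, and the design
decisions taken where the original system left choices open.

## The classifier

Each recording bout is `round(rateHz * durationS)` timestamped positions
in the cage frame (mm; origin at the front-bottom-left corner, z up — the
monitor itself fixes no axes, so this is the package's convention). The
rules act on consecutive-frame displacements `d_i = |P_{i+1} - P_i|`:

1. **Per-transition stage.** `d_i <= delta_rest` labels the transition
   resting; `d_i >= delta_fly` labels it flying; anything between is left
   pending. A transition's label is assigned to its *later* frame, and
   frame 1 inherits the first transition's label, so exactly one label per
   frame results.
2. **Window stage.** Frames are partitioned into tumbling (non-overlapping)
   windows of `window_n` frames aligned to the bout start; a final short
   window is adjudicated over its actual span. If the window's net
   first-to-last displacement is `<= delta_walk`, every pending transition
   in it becomes micro-movement, otherwise walking. Windows only ever
   adjudicate pending transitions: resting survives the window stage, which
   matters because the station rules below operate on resting runs.
3. **Station stage.** Every *maximal* run of consecutive resting frames of
   length `>= feed_min_points` whose positions all lie within
   `feed_radius` of the food center is relabeled feeding; likewise for
   drinking at the water station. "All positions inside the disk" was
   chosen over a centroid criterion; the two station disks are required to
   be disjoint at configuration time, so a run can never qualify for both.

Tie handling is frozen as `<=` for resting and the walking window and
`>=` for flying; with strict inequalities only measure-zero inputs would
change, but freezing them keeps the classifier bit-reproducible.

**Death rule.** A fly is flagged dead after a continuous resting span of
at least `death_hours` (default 5 h). Since no frames exist between bouts,
consecutive resting frames are chained into one span exactly when their
positions agree within `delta_rest` — within a bout this is implied by the
resting rule itself, and across an inter-bout gap it encodes "the fly did
not move while unobserved". Any non-resting frame or positional jump
breaks the span. The reported onset is the start of the earliest
qualifying span.

### Classifier parameters

| parameter | default | units | role |
|---|---|---|---|
| `delta_rest` | 1 | mm / frame | resting threshold (rule 1) |
| `delta_walk` | 5 | mm / window | micro vs walking net displacement |
| `delta_fly` | 20 | mm / frame | flying threshold |
| `window_n` | 5 | frames | tumbling window = 1 s at 5 Hz |
| `feed_min_points` | 25 | frames | minimum station dwell = 5 s |
| `feed_radius`, `drink_radius` | 10 | mm | station disks |
| `death_hours` | 5 | h | mortality rule |

The numeric threshold values are explicit package choices — the original
description fixes the rule *structure* and the 5-hour death constant, but
not the millimeter values — and everything downstream treats them as
configuration, not constants.

## The simulator

The generator exists to validate the classifier and the analytics against
known ground truth, so its design goal is controllability, not biological
fidelity. It is a six-state semi-Markov process on the 0.2 s frame grid:

* The fly alternates between **resting** episodes and **active** episodes
  (micro-movement, walking, flying, feeding, drinking, chosen with fixed
  probabilities; all dwells exponential, quantized to the grid).
* **Diurnal and age modulation** enter through the resting exit rate. The
  target fraction of time active is
  `f(h, d) = peakActivity * w[h]/max(w) * a(d)` with hourly weights `w`
  and age multiplier `a(d) = (d/18) exp(1 - d/18)` (rising over the first
  two weeks, peak at day 18, gradual decline). The exit rate inverts the
  alternating-renewal occupancy, `rate = f / (tau_active (1 - f))`, so
  realized activity — and hence distance — tracks the weights *linearly*
  instead of saturating at busy hours. Rest dwells are sampled under the
  piecewise-constant (per clock hour) hazard.
* The default weights put 90% of the weight mass in the 07:00–19:00
  lights-on phase and 50% in 15:00–19:00 with the maximum at 18:00 — the
  diurnal structure this class of monitor is designed to resolve. These
  are the packaged study conditions; the pipeline-recovery tests check
  that the full simulate–sample–classify–summarize chain reproduces them.
* **Displacement scales** are deliberately separated from the classifier
  thresholds by at least a factor of three in both directions: resting is
  2 µm/axis Gaussian tremor (blob-centroid scale for a motionless fly,
  small enough that integrated "noise distance" over a mostly-resting life
  stays below ~2% of path length); micro-movement oscillates with 1.8 mm
  amplitude about an anchor (per-step ~3.6 mm, net ~0 — grooming in
  place); walking moves 6 mm/step (30 mm/s) in straight clearance-checked
  legs; flying 60 mm/step (300 mm/s). Walking and flying redirect *before*
  walls — new directions need free straight-line clearance, preferring
  non-reversing headings — so step magnitudes are exact and wall
  reflections cannot silently compress displacements across thresholds.
* **Feeding/drinking are teleport-free**: a walking transit leg carries the
  fly to an anchor within 5 mm of the station, the dwell is resting-like
  jitter there (so the station relabeling rule is genuinely exercised),
  and another leg carries it away — preventing a post-dwell rest from
  merging into the station run.
* **Death** is a log-normal day (median 60 d, sdlog 0.35) snapped to the
  start of the next resting episode; the position freezes thereafter, and
  the cohort generator emits no bouts after death.

### Scale management

A dense 0.2 s lifetime trajectory would be ~17 M points per fly over
40 days, so `generateCohort()` separates the *episode timeline* (tens of
thousands of episodes per fly, generated exactly) from *step-level
realization*, which happens only inside scheduled bout windows. Within a
window, consecutive episodes chain through realized endpoints, so sampled
trajectories are continuous; between windows the position advances at
episode granularity (rest and micro keep their anchor exactly — which is
what death detection relies on — while long walks and flights mix to a
uniform cage point). `simulateLifetime()` realizes everything densely and
is the right tool below a few days.

All episode boundaries are snapped to the frame grid. This makes 5 Hz
sampling lossless, guarantees each inter-frame transition carries
single-state dynamics, and avoids floating-point drift between episode
times and sampling instants over multi-week horizons.

### What the simulator does not emulate

Exponential dwells (real rest bouts are heavy-tailed), walking on
surfaces (paths live in the cage volume), social behavior, inter-fly
variance beyond the death day, and detection noise in sampled positions
(the stereo module models that separately). Passing the recovery tests
therefore shows the *pipeline arithmetic* is right — that planted diurnal
shares, age peaks and cluster structure survive sampling, classification
and summarization — not that real flies behave this way.

## Stereo module

An idealized rectified parallel-axis pinhole pair replaces the original
(uncalibrated, undocumented) rig: both optical axes point into the cage,
depth from the camera plane is `Z = y + standoff`, and disparity is
`f B / Z` (defaults f = 800 px, B = 60 mm, standoff = 250 mm, chosen so a
±0.5 px detection error stays below 1 mm median 3D error across the
cage). Synthetic frames render the fly as a bright disk on a dark
background; detection takes the intensity-weighted centroid above an Otsu
threshold (EBImage), with a fixed-threshold override. Off-frame flies
yield a missing detection, treated downstream as no data. Lens
distortion, verging rigs and multi-blob tracking are out of scope.

## Summaries

Hourly matrices are day-of-life × clock-hour; with 2–3 one-minute bouts
per hour a cell is scaled by `3600 / recorded seconds` to estimate the
full-hour value (the raw-sum variant is available and is exactly additive
with bout distances). Hours without recordings are `NA`, never zero.
"Normalized" profiles default to peak normalization (max = 1) with a
share mode (sum = 1) used for the distance-share analyses; days start at
the experiment clock's midnight and daytime is `[lights_on, lights_off)`.
Rest runs reuse the death rule's gap bridging and are binned `<1`, `1–2`,
`2–3`, `>3` h. Survival uses Kaplan–Meier with flies alive at study end
censored.

## Clustering

Age-group profiles average per-fly six-behavior frequency vectors over
10-day intervals. Two dissimilarities are offered: Euclidean distance
between averaged profiles, and an optimal-matching edit distance (dynamic
program; classical constant costs, substitution 2, indel 1) between
per-group representative sequences (hourly modal labels). Linkage
defaults to average (the source material names none); `ward` maps to
Ward.D2. The automatic cut takes the number of clusters just below the
largest gap in merge heights. Branch significance in the original
presentation has no documented procedure, so the package substitutes
bootstrap monophyly support: flies are resampled with replacement, trees
rebuilt, and each reference node scored by how often its leaf set
reappears. `plantedArchetypeCohort()` provides the planted-partition
fixture — three life phases whose behavior mixes follow the canonical
ordering (mid-life highest in walking/flying, old age highest in
resting/micro-movement) — used to verify that the automatic cut recovers
exactly three clusters.

## Numerical and testing choices

* Bout logs serialize positions at 3 decimals (µm) and times at 1 decimal;
  the round-trip property is exact at that precision.
* Per-fly seeds derive from the master seed as
  `(seed * 1000003 + i * 7919) mod (2^31 - 1)`, keeping streams
  reproducible yet distinct.
* Cage defaults to 150 × 150 × 150 mm with food/water on the floor and
  "top of the cage" meaning the top quarter (`top_fraction = 0.25`);
  none of these are fixed by the source system, all are configuration.
* Problem sizes in the test suite: classifier-vs-brute-force equivalence
  on 170 random 60/23-frame bouts; OM-vs-enumeration on all pairs of
  length ≤ 4 plus random longer pairs cross-checked against `utils::adist`;
  stereo end-to-end on 150 rendered positions and 1000 projection round
  trips; pipeline recovery on one 8-fly × 40-day cohort (the same
  conditions `scripts/acceptance.R` reruns) and the planted 16-fly
  clustering cohort. Sizes were chosen to exercise every code path while
  keeping the default suite in the low minutes.

## Known limitations

The classifier is deliberately memoryless apart from the window stage —
no smoothing or learned thresholds. Gap bridging assumes a motionless fly
between bouts; a fly that leaves and returns to the same spot within
`delta_rest` during an 18-minute gap is indistinguishable from one that
never moved. Hourly full-hour scaling assumes within-hour stationarity of
activity. The OM distance uses constant costs; state-dependent cost
matrices are out of scope.
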