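---
title: "Methods: trajectory-based zebrafish behavioral phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-based zebrafish behavioral phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebratrax)
```

## Scope and data model

zebratrax quantifies zebrafish behavior from 2-D centroid tracking: a
time-ordered series of (x, y) positions in millimetres at a nominal frame
rate (25 fps by default), one fish (or one shoal) per arena. Video tracking
itself happens upstream; the package starts from the exported centroid
table. Three object families carry the analysis:

* `arena_geometry` — the container (circular well/dish or rectangular
  tank), its named regions, and the width of the "edge band" used by
  wall-related analyses. Circular arenas are centred at the origin;
  rectangles use a lower-left origin, x right, y up, all lengths in mm.
* `light_schedule` — contiguous light/dark epochs labelled
  `adaptation`/`L0`/`L1`/`D1`/`L2`/`D2` (or a single open-field epoch).
* `swim_trajectory` — per-frame positions with explicit timestamps and a
  missing-frame mask, bound to an arena.

Two published timings of the larval light/dark assay circulate: a
figure-style protocol (20 min adaptation, 40 min baseline light, then two
5-min-light/5-min-dark cycles; 80 min) and a methods-style protocol (55 min
light plus the same two cycles; 75 min). `make_pmr_schedule()` provides
both as `"figure"` and `"methods"`; the package deliberately declares
neither canonical, and all downstream code works from epoch labels rather
than absolute minutes.

## Pre-processing choices

**Jitter deadband.** Tracker centroid noise shows up as sub-millimetre
frame-to-frame displacement that would otherwise accumulate into spurious
travelled distance. Commercial trackers expose a unit-less sensitivity
threshold for this; a device setting is not portable, so
`suppress_jitter()` re-expresses it as a physical deadband: the position is
held until the fish moves at least `min_step_mm` (default 0.2 mm, suited to
larval centroid noise at 25 fps) from the last accepted position. The
operation never increases path length and is idempotent. It exists to
remove *tracking* noise: applied to noise-free simulated centroids it
biases distances downward (more strongly at low speed, which inflates
dark/light ratios), so simulator-validation analyses run on raw
trajectories while real-data pipelines keep the deadband on.

**Gap repair.** Runs of up to 5 consecutive missing frames are linearly
interpolated; longer dropouts stay missing and split every
bout/segment-level analysis, so a lost fish cannot fabricate motion.

**Boundary tolerance.** Points up to 0.5 mm outside the arena are clamped
onto the wall (lens/calibration overshoot); anything further is flagged
missing with a warning.

## Locomotion and the photomotor response

Distance is the chord sum over consecutive non-missing frames; steps
straddling a window edge contribute proportionally to the overlapped
fraction of their duration, so windowed distances are exactly additive.
`bin_activity()` pools distance into left-closed right-open 1-min bins (the
conventional pooling for this assay) and labels each bin by the epoch
covering its midpoint; bins longer than the shortest epoch are refused
rather than labelled ambiguously. The photomotor response ratio of a cycle
(`light_dark_ratio()`) is the dark-phase mean per-minute distance divided
by the light-phase mean of the same cycle. A zero light-phase mean makes
the ratio undefined; it is reported as `NA` with a flag instead of raising,
because a fish that froze through a light phase is data, not an error.

## Zone metrics

Thigmotaxis contrasts a concentric inner disk with the outer ring of a
circular well. The published figures do not dimension the zones, so the
inner-zone radius fraction is configurable with a default of 0.5 (25% of
the arena area). Dwell time is frame-weighted; distance is assigned to the
region containing each step's midpoint (steps are never split — the error
is bounded by one step length and the rule is deterministic). Region
membership is boundary-inclusive, which fixes the tie-break for points
exactly on a zone boundary. For the social-preference tank the `"social"`
region defaults to the strip within 70 mm of the divider wall (one third of
the 210 mm tank length, configurable); the published "distance away from
the social area" is reported as the complement of the in-region distance
fraction, a deliberate reading of an ambiguous phrase. Occupancy heatmaps
accumulate frame dwell seconds on a square grid (5 mm default for tanks)
and conserve total time to within one frame interval.

## Repetitive-behavior classifiers

Three rule-based classifiers mirror the published definitions, each with
stated numeric conventions where the prose under-determines them:

**Stereotypic (small-circling) swimming** — within a continuous swimming
interval (smoothed speed at or above 1 mm/s, sub-0.2 s dips bridged), a
maximal sub-interval longer than 5 s whose spatial span stays below 30 mm.
"Maximum movement distance" is read as the maximum pairwise distance among
the interval's positions (spatial span), not net start-to-end displacement:
a full lap of the tank ends where it began and must not count as confined.
Bouts grow greedily left to right and are truncated before the frame that
would push the span to 30 mm; the implementation is checked against an
all-pairs distance-matrix oracle.

**Large circling** — the signed angle about the arena centre is accumulated
over frames inside the edge band; every monotone accumulation of 2*pi
emits one loop, labelled by orientation (counterclockwise positive). The
accumulation resets when the direction reverses by more than pi/2 or the
fish leaves the band for over 0.5 s; both smoothing constants are
configurable, and a band-free mode exists for sensitivity analysis.
Loop counts equal the winding number of smooth monotone wall paths.

**Back-and-forth excursions** — within the edge band of a rectangular
tank, an excursion that visits one wall or two adjacent walls, travels at
least 50 mm of path *and* of tangential displacement away from its origin,
and returns to within 15 mm of it. Three refinements keep the rule meaning
"moving one time on an edge and returning": a tangential-displacement
requirement (a perpendicular wall bounce travels far but not *along* the
edge), a tortuosity cap of 3 (a single out-and-back has path about twice
its depth; prolonged meandering that happens to close a loop does not), and
a wall-hugging requirement (at least 70% of frames within the inner half of
the band, rejecting oblique band crossings that turn at the wall).
Opposite-wall traversals never qualify. The 50 mm floor, 15 mm return
radius, cap, and hugging fraction are package conventions, configurable and
stated here because the source prose gives no numbers.

Edge bands default to roughly one body length of the animal the arena is
built for: 2 mm (7-dpf larvae in a well), 4 mm (15-dpf dish), 25 mm
(mating tank), 35 mm (adult novel tank).

## Shoaling

The interindividual distance of a k-fish shoal is, per frame, the mean of
all k(k-1)/2 pairwise distances; the scalar index is its time average.
Frames missing any fish are dropped rather than interpolated — a pairwise
mean over a partial frame is biased toward whichever fish remain — and the
dropped fraction is reported. Whether the published index is a time average
or a per-fish average is not stated; the time average of the pairwise mean
is the convention here.

## The swim simulator

Every analysis above is validated against an agent-based simulator
(`simulate_fish()`, `simulate_shoal()`, `make_cohort()`) that emits
ground-truth labels. The agent is a discrete-time correlated random walk:
per-frame speed is gamma distributed (mean and shape per group), heading
receives wrapped-normal noise and is then steered by convex blending toward
the nearest wall's tangent/approach direction (weight `wall_bias`), the
social-region centre (`social_weight`), and the shoal centroid
(`cohesion`); dark epochs multiply speed by `dark_multiplier`. Walls
reflect the position, after which the heading is redirected along the
inward wall normal with angular scatter (SD 0.8 rad). This collision-
avoidance turn is a deliberate modelling choice: specular boundaries act as
corner retro-reflectors and make the walk retrace itself along walls far
more often than animals do, which would blur the very wall behaviors the
classifiers target. All random draws happen in R's RNG before the compiled
walk loop runs, so a single integer seed fully determines every trajectory;
cohort members get seeds by fixed splitting, making cohorts reproducible
independent of group size.

Injected bouts temporarily override the walk with label-specific
kinematics: confined jitter in a 7 mm-radius disk for 10-15 s
(stereotypic; at least twice clear of the 30 mm/5 s thresholds, and placed
clear of the edge band so a confined bout does not double as a wall
event), wall-following laps at half-band inset with a 0.4-lap overshoot so
a one-loop accumulation still completes after any reversal backlash
(circling), and a 100 mm out-and-back along a wall approached
perpendicularly from outside the band, retracing its entry on exit so the
return-to-origin is well defined (back-and-forth). A `"hard"` mode
generates near-threshold bouts for sensitivity work. The ground-truth log
records every injected interval.

What the simulator does *not* emulate: burst-glide (saltatory) larval
swimming, posture and tail kinematics, inter-fish collisions, thermal or
acoustic startle, and habituation over the session. Passing recovery tests
therefore show the *analysis code* is correct and well-calibrated on data
satisfying its assumptions — not that the rules capture everything real
fish do.

## Group statistics

`compare_groups()` is the unpaired two-sided Student's t test
(equal-variance pooling, matching the usual reporting of behavioral
panels; Welch by flag), with means, SEMs and the star convention
(`*` < 0.05 through `****` < 0.0001). Zero pooled variance is handled
explicitly (t = 0, p = 1 when means agree; p = 0 otherwise) rather than
erroring on degenerate small cohorts. No multiple-testing correction is
applied across behavioral panels, and the report says so. The unit of
analysis is the fish (or the shoal), never the bin.

## Validation problem sizes

The packaged checks run at sizes chosen to give tight Monte-Carlo error
while staying quick on a laptop: 200 random-walk windows (up to 500 frames)
against the span oracle and 100 wall-following paths against the winding
oracle; 100 seeded 5-min cohort runs for classifier recall/precision;
200 simulated larvae for dark-multiplier recovery (sampling error about
0.5%); 50 paired seeds for the social and cohesion orderings; 1000
simulated null cohorts for t-test calibration (binomial SE about 0.7
percentage points). The same computations at larger sizes only shrink the
Monte-Carlo error.

## Known limitations

* The classifiers are rule-based; fish behavior that genuinely satisfies a
  rule (a spontaneous clean out-and-back, wall-following laps by a
  strongly thigmotactic fish) is counted, whatever its motivation.
* The back-and-forth conventions (50 mm floor, 15 mm return, tortuosity,
  hugging fraction) are package choices; sensitivity to them should be
  checked before cross-study comparisons.
* Heatmaps are raw dwell grids; no kernel smoothing is applied.
* The simulator's dark-phase response is a pure speed multiplier; real
  larvae also change turning statistics at light transitions.
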