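---
title: "From strides to street maps: methods behind stridemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From strides to street maps: methods behind stridemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridemap)
```

`stridemap` implements a two-stage pipeline for wearable lower-limb
sensing. Stage one turns thigh- and shank-mounted IMU recordings into a
sequence of classified strides (level walking, stair ascent, stair
descent). Stage two attaches WGS84 positions to those strides and grows a
geographic path network incrementally from many walks, so that a
lower-limb assistive device can later look up which locomotion mode a
place has historically demanded. This vignette explains the models, the
tunable parameters, the synthetic-data conditions the tests run under, and
the design decisions that were genuinely open.

## Stride segmentation

Human gait is periodic, and per-cycle statistics carry more class signal
than fixed-length windows, so the classifier operates on one full stride
of the instrumented leg at a time. Stride boundaries come from the thigh
pitch angle alone: near heel strike the thigh inclination reaches its
per-cycle maximum, so filtered local maxima of that one channel delimit
strides. The peak filter has three thresholds:

* `prominence` (0.2 rad) — rejects noise wiggles riding on the main peak;
* `min_height` (1.6 rad) — absolute height a heel-strike peak must reach
  under the sensor mounting convention assumed here, which doubles as a
  stance-phase rejector;
* `min_separation` (16 samples) — two heel strikes of the same leg cannot
  be closer than about half a second at the nominal 30 Hz rate. The unit
  is deliberately samples, not seconds: detection operates on the raw
  sample grid without resampling, and users of other rates can override
  the value.

Consecutive peaks closer than `max_cycle_duration` (2 s) bound one stride
window; longer gaps are standing periods and produce no window, so a
recording with pauses yields fewer windows than peaks. Peak plateaus
(exactly equal neighbouring samples, which the synthetic waveform can
produce at 30 Hz) resolve deterministically to the plateau's first sample.
The prominence search treats only *strictly* higher samples as competing
terrain, so a two-sample plateau does not zero its own prominence.

## Stride features and scaling

Each window is summarised by ten numbers: minimum, maximum, mean,
standard deviation, and range of the shank and thigh sagittal
inclination. Gyroscope and accelerometer channels are ingested and
round-trip through the CSV trial format, but are excluded from the
feature vector — the inclination statistics are the selected feature set.
Standard deviation uses the population convention (divide by *n*): the
window is treated as the complete cycle rather than a sample from one.

Features are scaled to the unit interval by a min–max scaler. Two
decisions matter for honest cross-validation:

* the scaler is fitted on the **training fold only** of each
  cross-validation run and applied unchanged to the test fold, so no
  information leaks across the split;
* test values outside the training range are **not clipped** (they map
  outside `[0, 1]`), preserving ordering; a zero-range training column
  maps everything to 0 to avoid a division by zero.

## Classifiers and evaluation protocols

Two model families are provided. The production model is a support vector
machine in one-vs-rest configuration: one RBF-kernel binary SVM per class
(`e1071::svm`, cost 1, `gamma = 1/10`, both exposed), predicting by
highest decision score with ties broken in the fixed class order walk <
stairs_up < stairs_down. The baseline is a depth-3 decision tree
(`rpart`). No class re-weighting is applied even though walking strides
are about twice as frequent as either stair class in the default
schedule.

Evaluation uses two protocols. Leave-one-subject-out holds out all
strides of one subject per run; leave-one-trial-out holds out one trial
per run while **also excluding the tested subject's other trials from
training**, so a subject never informs their own test run. Accuracy is
the overall fraction correct; precision, recall and F1 are macro-averaged
over the three classes with the zero-division-means-zero convention.
Per-run metrics are aggregated as mean/std/min/max and the per-run 3×3
confusion matrices (rows true, columns predicted) are summed. To make
reports independent of row order, samples are canonically sorted before
fold construction; with the seed fixed the whole evaluation is
bit-reproducible.

## Georeferencing

Phone GPS delivers fixes more slowly than steps occur, so each stride's
position is linearly interpolated in time between the bracketing fixes,
per coordinate, in plain latitude/longitude degrees — at step-scale
distances the curvature error of linear interpolation is far below GPS
noise. A stride is anchored at its **start** time (the heel strike that
opens it); strides outside the fix span are dropped rather than
extrapolated. IMU and GPS clocks are assumed aligned upstream; a constant
offset parameter is provided for convenience.

## The map layer

The map is a bidirectional graph: typed polyline paths (trail, walk,
stairs up/down; stairs carry a `stair_count`) joined by crossings. Each
path records a `merge_count` — how many traces it aggregates — which is
both the evidence weight for averaging and the criterion for pruning.
Referential symmetry (every crossing connection is mirrored by the path's
own crossing field) is a store invariant checked by an audit operation
after every insertion.

Coordinates at rest are WGS84 (longitude, latitude) per GeoJSON; all
metric work happens in a local equirectangular tangent plane centred on
the data. Over the sub-kilometre extents of a pedestrian network this
projection is exact to millimetres and cheaply invertible, which matters
because averaged geometry must map back to WGS84. The one place where
projection distortion would be visible — splitting a path at a stated
arc-length position — instead measures arc length geodesically
(`geosphere::distGeo`), so split lengths are exact to well under a
centimetre. Persistence is a GeoJSON FeatureCollection rather than a
spatial database; the store contract (insert, delete, update, get,
bounding-box query) leaves a database backend open.

## Inserting a trace

Insertion follows a fixed sequence; it is atomic (any failure leaves the
store untouched, mirroring a transactional backend):

1. **Simplify.** Loops are removed first — the polyline is cut wherever it
   properly crosses itself or revisits an earlier vertex (a figure-eight
   anchored at its waist is the canonical case) — and only then are
   vertices thinned by Douglas–Peucker, because thinning can straighten
   out the very vertex at which the polyline revisits itself. No removed
   vertex deviates more than `simplify_tolerance` (0.5 m).
2. **Look up candidates** by bounding-box intersection, snapshotted
   before any piece is stored so a trace can never match parts of itself;
   a merge count must record independent traversals.
3. **Match.** The segment is resampled at `resample_spacing` (1 m); a
   sample matches a candidate when it is within `match_distance` (5 m)
   *and* the local headings differ by at most `match_angle` (45°) modulo
   180° — paths are bidirectional, so an anti-parallel retracing matches
   while a perpendicular crossing does not. Headings are estimated over a
   ±`heading_window` (5 m) arc: with 2 m GPS noise at 1 m spacing,
   per-segment directions are meaningless. Overlapping stored fragments
   are disambiguated with hysteresis (stay with the current candidate
   while it still matches), and runs are cleaned: matched runs shorter
   than `min_match_length` (3 m) are demoted, unmatched gaps shorter than
   that between runs of the same candidate are bridged.
4. **Split and merge.** Where a match starts or stops inside a stored
   path, the path is split there (the cut point is the projection of the
   piece boundary onto the candidate, so the two coincide); numeric
   properties are redistributed proportionally to length, with stair
   counts rounded to integers that sum exactly. The matched stretches are
   then merged: both are resampled, paired by arc-length fraction
   (re-orienting an anti-parallel partner), and averaged vertex-wise with
   weights equal to the merge counts, so an established path moves only
   slightly toward a new trace. Properties average with the same weights;
   merge counts add. Paths of different types refuse to merge — a stairs
   path is not the same facility as the adjacent walkway — unless
   `type_aware = FALSE` restores the untyped mode used for plain trails.
5. **Connect.** A connector crossing is placed at every boundary between
   matched and unmatched stretches. Where the candidate was split, the
   split's crossing *is* the connector (anchoring there, not at the
   trace-side boundary point, keeps a three-way branch at one crossing
   instead of two). Crossings within `crossing_snap` (2 m) are reused
   rather than multiplied, and free path endpoints that meet within the
   snap radius are joined — this is how junctions form where traces of
   different paths abut. A crossing is only materialised where at least
   two path ends meet; a lone trace terminus stays bare.

Unmatched stretches shorter than `min_match_length` are discarded rather
than inserted: they are noise overhangs (a trace running a couple of
metres past the stored backbone) and would litter the map. Larger
unmatched stretches become new paths with merge count 1.

`prune_unmerged(store, min_merges)` implements the evidence rule for
spurious traces: a path never confirmed by a second traversal — the
signature of a multipath reflection off a building — is removed, along
with crossings left unconnected.

Map quality against a reference network uses two standard scores:
geometric correctness (fraction of constructed length within a buffer of
the reference paths) and topological correctness (fraction of reference
crossings with a constructed crossing within the buffer).

## Synthetic study conditions

The real study data behind this pipeline is not publicly distributable,
so the package carries generators that emulate its structure; all tests
and the acceptance script run on them.

**Gait.** Thigh inclination is a rectified sinusoid peaking once per
stride, with class-conditional amplitude and period (walk 1.8 rad / 1.1 s,
stairs up 2.1 rad / 1.4 s, stairs down 1.9 rad / 1.2 s — all peaks above
the 1.6 rad detection threshold). The shank waveform differs between
classes in amplitude, baseline and phase (ascent leads, descent lags), so
the ten inclination features separate the classes: those shape parameters
were chosen once, as plausible contrasts a real shank would show, before
any evaluation was run. Gaussian noise (sd 0.05 rad) is added per sample;
per-subject variability is a multiplicative amplitude factor (sd 0.08)
drawn deterministically from the subject identifier. The effective thigh
amplitude is clamped to stay at least 3 noise standard deviations above
the detection threshold, so stride detection remains well-posed for every
drawn subject — without the clamp, a 2-sigma subject would silently lose
all walking strides. Windows that straddle an activity transition carry
mixed content and are excluded from labeled datasets, mirroring how
manually labeled activity spans exclude the transitions between them.
Gyroscope/accelerometer channels carry waveform derivatives plus noise so
the full trial format is exercised.

**Traces and networks.** Two ground-truth templates exist: a corridor —
a 46 m hallway flanked by two 21-step staircases (3 typed paths, 2
crossings) — and an n×n campus grid of 50 m trail blocks. GPS traces
sample a route at walking speed (1.3 m/s, 1 s fixes) with isotropic
Gaussian noise (default sd 2 m); with a configurable probability a
contiguous run of about 15% of the fixes is displaced sideways by 25 m,
emulating a multipath reflection. The displacement is perpendicular to
the route because a shift along it would hide inside the path.

**What passing tests do and do not show.** The generators produce cleanly
periodic gait and isotropic GPS noise. Real recordings have soft tissue
artefacts, asymmetric gait, missing samples, and spatially correlated GPS
error along street canyons; real stair bouts change walking speed, and
real networks have open plazas that this algorithm does not model.
Passing the synthetic recovery tests therefore demonstrates that the
pipeline's machinery is correct under its stated assumptions — near-ideal
class separation gives LOSO accuracies near 1.0, which should be read as
a property of the synthetic separation, not a claim about field
performance.

## Problem sizes and numerical choices

The test suite and acceptance script use a 20-subject cohort (~840
strides), 100 seeded step-detection trials, a four-path grid with five
traces per path for network recovery, and twenty 50-operation randomized
store sequences for the consistency audit — sizes chosen so the whole
suite completes in well under a minute while keeping every stochastic
check comfortably away from its threshold. Other fixed numerical choices:
Douglas–Peucker keeps endpoints exactly; the candidate scan samples at
1 m and therefore locates match boundaries to about one sample; merge
order within a group is descending merge count then ascending id (the
weighted average makes order nearly neutral, the fixed order makes it
deterministic); degenerate matches whose footprint on the candidate is
shorter than the snap radius fall back to a fresh insert rather than a
meaningless merge.

## Known limitations

* The heading criterion needs ~5 m of arc to stabilise, so matches
  erode by up to half a heading window at sharp corners, and very short
  true spurs (< 3 m) are invisible by design.
* Merged geometry ends can drift slightly from their crossing's stored
  location (the crossing is authoritative); a cleanup pass that re-ties
  path ends to crossings would remove the cosmetic gap.
* Repeated insertions fragment a corridor into several collinear pieces
  separated by crossings; pruning removes unconfirmed fragments but no
  consolidation of confirmed collinear neighbours is attempted.
* Open areas (plazas) produce arbitrary path tangles; detecting and
  abstracting them is out of scope.
* The CLI's model persistence uses RDS, which is R-specific; the map and
  step layers use portable GeoJSON/GPX/CSV.
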