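---
title: "Geometric hand-face contact detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric hand-face contact detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetouch)
```

## The problem and the model

`facetouch` monitors hand-to-face contact behavior from depth-camera body
tracking. The input is a stream of 32-joint skeletons in camera space
(millimeters; x right, y down, z away from the sensor), one per tracked body
per frame. The detector is deliberately geometric — no learned components —
so it needs no training data, works with gloves and masks, and its behavior
is fully explainable by three constructions:

1. **Head sphere.** Center at the midpoint of the two ear joints, diameter
   equal to the inter-ear distance $d$. Every threshold scales with $d$, so
   the detector adapts to head breadth without calibration: over the
   5th–95th percentile head breadths of a 40-year-old American male
   (14.8–16.8 cm) the contact radius spans 10.36–11.76 cm.
2. **Contact volume.** A concentric sphere of radius $0.70\,d$. A frame is a
   contact iff a thumb joint lies inside it (boundary inclusive). The 0.70
   ratio is an empirical sensitivity/specificity tradeoff: widening it adds
   false contacts, narrowing it misses true ones. It is a config parameter
   (`detection_config()`), as is the 0.75 below.
3. **Area classification.** A contact is attributed to the nearest of six
   face landmarks (nose, synthesized mouth, both eyes, both ears),
   partitioning the sphere like a Voronoi diagram — unless the nearest
   landmark is farther than $0.75\,d$, in which case the touch is `low_risk`
   (far from mucous membranes). Mouth and nose are merged afterwards, giving
   six classes.

The per-frame classifier is a pure function of one frame; all temporal
structure (events, warnings, reports) is produced downstream by run-length
grouping, so the detector itself assumes no frame rate.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `contact_ratio` | 0.70 | — | contact radius as a fraction of inter-ear distance |
| `lowrisk_ratio` | 0.75 | — | low-risk cutoff as a fraction of inter-ear distance |
| distance threshold | 1000 | mm | interpersonal pelvis–pelvis alert distance (1 m rule) |
| match `tolerance_s` | 0.5 | s | midpoint tolerance for zero-overlap event matching |
| `min_frames`, `merge_gap_s` | 1, 0 | frames, s | optional event smoothing, off by default |

With the defaults the low-risk threshold strictly exceeds the contact
radius, so every in-volume touch near a landmark is attributable.

## Design choices where the design was open

- **Mouth landmark.** The 32-joint skeleton has no mouth joint, yet the
  classifier distinguishes a mouth area. We synthesize it as the nose offset
  by $0.25\,d$ along the head→neck axis, which lies below the nose for any
  head pose (rotation-equivariant by construction). The stakes are low
  because mouth and nose merge into one class.
- **Boundary inclusivity.** Distances exactly equal to a threshold count as
  inside / at-risk, favoring sensitivity for risk contacts.
- **Bimanual contact.** When both thumbs are inside the volume the one
  nearer the sphere center triggers; exact ties go to the left thumb. Only
  thumb joints are tested — hand and handtip joints are ignored.
- **Landmark ties.** Equidistant landmarks resolve by the fixed priority
  nose > mouth > right_eye > left_eye > right_ear > left_ear — a
  probability-zero event in real tracking data, but it makes the classifier
  deterministic.
- **Degraded frames.** A frame lacking either ear or both thumbs cannot be
  processed; it is labeled no-contact with `degraded = TRUE` and tallied in
  the report rather than interpolated, since body tracking loses exactly
  these joints when the hand is at the face.
- **Event timing.** An event's end is the last contact frame's timestamp.
  Reported durations add one median frame interval to the span, so a run of
  $k$ frames at rate $f$ contributes $k/f$ seconds and reports of
  concatenated streams add exactly.
- **Event matching.** The evaluation protocol assumes events are aligned to
  human annotations; we match each truth event to the prediction with
  maximal temporal overlap (greedy, descending overlap, each prediction used
  once), falling back to nearest midpoints within 0.5 s when nothing
  overlaps. Unmatched predictions are *spurious* and stay out of the
  confusion matrix, whose columns are truth events only; unmatched truth
  events score `no_detection`.
- **Confusion-matrix orientation.** Columns are truth classes and rows
  classifier classes — the opposite of several common conventions — and the
  classifier's `occlusion` row doubles as "no event emitted", because the
  detector never outputs an occlusion label: a truth occlusion it stayed
  silent on is a correct (diagonal) outcome, a missed contact lands in its
  truth column of that row.
- **Undefined metrics.** Per-class precision/sensitivity with empty margins
  (0/0) are reported as `NaN` and flagged, never coerced to 0 or 100.
  Cohen's Kappa with $p_e = 1$ is likewise flagged.
- **Distance rule.** Full 3D Euclidean distance between pelvis joints,
  strict `< 1000 mm` to alert (exactly 1 m is compliant). Alerts stay
  per-frame; they are counted, not grouped into events.

## The simulator: what it emulates, and what it does not

The synthetic-data module emulates the validation geometry: one (or more)
bodies standing 2 m from the sensor mounted at 1.7 m, executing scripted
gestures — contacts to each face area, low-risk touches (inside the contact
volume, beyond the low-risk threshold from every landmark), face occlusions
(thumb on the head-to-sensor line at 1.5× the contact radius: occluding in
projection, never in geometric contact), and idle spans. Head breadth
presets `p05`/`p50`/`p95` (14.8/15.7/16.8 cm) set the anthropometric range.

Trajectories are piecewise linear at 30 fps: rest pose at hip height
(≈ 0.45 × body height below the head, far outside all thresholds), an
approach routed through a staging point radial to the head so the entry
path's nearest landmark is unambiguous, a hold 10 mm beyond the target
landmark, and a mirrored return. Noise is isotropic Gaussian jitter per
joint per frame (default 5 mm — small against the ≥ 100 mm contact radius;
its true magnitude in depth tracking is not characterized) plus optional
dropout of face/thumb joints. Ground truth derives from the noiseless
trajectory; identical seeds give byte-identical streams.

What the simulator does **not** model: biomechanical arm kinematics (only
the gesturing hand chain moves), correlated or pose-dependent tracking
error, body rotation and torso occlusion, or the gesture-choice behavior of
a real person (the class mix is a parameter). Passing the simulation-based
tests therefore demonstrates the correctness of the geometry, segmentation
and scoring machinery under controlled noise — not field performance of the
sensor stack.

## Numerical choices and degenerate inputs

- Millimeters everywhere internally; head breadths are quoted in cm at the
  interfaces and converted.
- Serialization is deterministic: canonical joint order, 3 decimals for mm,
  6 for seconds; written files are byte-stable and round-trip within that
  precision.
- Zero inter-ear distance is a degenerate-geometry error; a missing ear is a
  degraded frame, not an error, inside the labeling pipeline.
- Empty streams, empty label buffers and empty event lists all produce
  well-formed zero reports rather than errors.
- Equal-overlap matching candidates resolve by earlier truth start, then
  earlier prediction start.

## Problem sizes used by the test suite

The suite validates the frame classifier against an independent
straight-line oracle on 10⁴ random frames (thumbs uniform in a 0.5 m cube
around the head), recovers noiseless scripts across all three anthropometric
presets with event-level κ = 1, and runs a 60-event simulated validation
session (jitter 5 mm, fixed seed) through detect → monitor → evaluate. The
jitter-degradation property uses 20 seeds at jitter ∈ {0, 5, 15, 40} mm on a
six-gesture script. The reference confusion matrix shipped with the package
(575 events) exercises the metric stack at its published scale.

## Known limitations

- The detector reads only thumb joints; contacts led by other fingers are
  detected only insofar as the tracked thumb follows them.
- Frame labels are independent per frame, so tracking jitter near the
  contact boundary fragments events (visible in the worked example); the
  optional `merge_gap_s`/`min_frames` smoothing exists but defaults to off
  to keep the raw behavior observable.
- Occlusion is defined behaviorally (no contact emitted); the evaluation
  relies on truth annotations to distinguish a correctly-ignored occlusion
  from a missed contact.
- The interpersonal-distance check requires a tracked pelvis per body and
  does not fuse identities across tracking dropouts.
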