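# facetouch

Unconscious hand-to-face contacts move pathogens from contaminated hands to
the oral, nasal and periocular mucosa, and monitoring how often workers touch
their face — and where — is part of auditing hygiene behavior at fixed
workstations (production lines, checkouts, triage desks). `facetouch`
implements a complete, hardware-independent pipeline for that task: it
consumes time-stamped streams of 3D body-joint coordinates (the 32-joint
skeleton emitted by Azure-Kinect-class body tracking), detects and classifies
hand–face contact gestures with purely geometric heuristics (no machine
learning), aggregates them into events, reports, and interpersonal-distance
alerts, and quantifies event-level agreement with a human observer. A
synthetic skeleton-gesture simulator makes the whole system testable without
a depth camera.

## The method

For each frame, the head is modeled as a sphere centered at the midpoint
**c** of the two ear joints with diameter equal to the inter-ear distance
*d*. Two thresholds scale with *d* so they adapt to the person's
anthropometrics:

- **contact radius** `r_c = 0.70 d` — a thumb joint **p** with
  ‖**p** − **c**‖ ≤ r_c marks the frame as a hand–face contact. Over the
  5th–95th percentile head breadths (14.8–16.8 cm) this radius spans
  10.36–11.76 cm.
- **low-risk threshold** `r_l = 0.75 d` — a contact farther than `r_l` from
  every face landmark is a *low-risk* touch, away from mucous membranes.

Contact frames are classified by the nearest face landmark (nose, synthesized
mouth point, eyes, ears), partitioning the head sphere like a Voronoi
diagram; the mouth and nose areas are then merged, yielding six classes:
`mouth_nose`, `right_eye`, `left_eye`, `right_ear`, `left_ear`, `low_risk`.
Runs of identically labeled contact frames become contact events; pelvis
distances between tracked bodies below 1 m raise alerts.

Evaluation matches predicted events to ground-truth annotations by maximal
temporal overlap and builds a confusion matrix in the convention *columns =
truth, rows = classifier*, where the classifier's `occlusion` row holds the
events for which it emitted nothing (it never detects face occlusions by
design). Per-class accuracy, precision and sensitivity, overall accuracy
(trace/total) and Cohen's Kappa

κ = (p_o − p_e) / (1 − p_e),  p_e = Σᵢ rowᵢ·colᵢ / N²

are computed for the 7-class layout and for the clustered
risk-contacts / no-risk-contacts / occlusion layout.

## Worked example

The package ships the 7-class confusion matrix from a 575-event laboratory
validation of the detector against a human observer:

```r
library(facetouch)
cm <- validation_confusion()
cohens_kappa(cm)
#> Cohen's Kappa = 0.764 (p_o = 0.7983, p_e = 0.1437): substantial agreement
overall_accuracy(cm)
#> [1] 79.82609
cohens_kappa(cluster_matrix(cm))   # risk / no-risk / occlusion
#> Cohen's Kappa = 0.851 (p_o = 0.9096, p_e = 0.3919): almost_perfect agreement
```

So at the six-contact-class level the detector agrees substantially with the
observer (79.8% of 575 events on the diagonal), and distinguishing risk from
no-risk contacts it reaches 91.0% accuracy with almost-perfect agreement.

Simulating a session and running the full pipeline:

```r
n <- c(mouth_nose = 3, right_eye = 2, left_eye = 2, low_risk = 2, occlusion = 2)
sim <- generate_validation_set(n, noise = noise_model(5, 0, 7))  # 5 mm jitter
labels <- label_stream(sim$stream)
events <- group_events(labels)
evaluate_events(events, sim$truth_events)
#> <evaluation_result> 11 truth events | overall accuracy 100.00% | kappa 1.000 (almost_perfect)
#>   clustered (risk/no-risk/occlusion): accuracy 100.00% | kappa 1.000 (almost_perfect)
build_report(labels, events)
#> <attitude_report> span 21.40 s | 21 contact events (3532.7/h) | 0 degraded frames | 0 distance alerts
```

Every truth event (including the two occlusions, correctly left undetected)
is matched and labeled correctly; note how 5 mm of joint jitter fragments the
boundary-grazing low-risk touches into several short detected events — the
matcher pairs each truth event with its maximal-overlap detection, so
event-level agreement stays perfect while the report counts 21 raw runs.

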