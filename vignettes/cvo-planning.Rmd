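---
title: "Planning geometry and validation methods for curved varus osteotomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning geometry and validation methods for curved varus osteotomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvoplan)
```

# The rotation model

Curved intertrochanteric varus osteotomy (CVO) cuts the proximal femur
along a circular arc between the greater and lesser trochanters and rotates
the head-and-neck fragment into varus about the arc's center.  Because the
cut is an arc of a circle and the fragment rotates about that circle's own
center, the two fragments stay congruent along the cut; the whole kinematic
is a single 2D rotation.

In the arc-center frame (+x lateral, +y proximal) the femoral-head center
sits pre-operatively at $(-A, B)$, where $A$ is the lateral shift and $B$
the distal shift of the arc center relative to the head center, both in mm.
A varus rotation by $\theta$ maps it to

$$H' = (-A\cos\theta - B\sin\theta,\; -A\sin\theta + B\cos\theta).$$

Clinically the head stays seated in the acetabulum, so the femur (and the
leg) translates by $H - H'$; its vertical component is the **leg
shortening** and its horizontal component the **femoral lateralization**:

$$s(\theta) = A\sin\theta + B(1-\cos\theta), \qquad
  \ell(\theta) = -A(1-\cos\theta) + B\sin\theta.$$

`predict_shortening()`, `predict_lateralization()` and `head_post()`
implement these closed forms; `rotate_points()` is the underlying rigid
rotation, and the test suite checks the closed forms against an explicit
rotation construction rather than against themselves.

Assumptions worth stating: the model is two-dimensional (a true AP
projection), the fragments are rigid, the cut introduces no translation
between fragments, and the head does not migrate in the acetabulum between
radiographs.  $\theta$ is in degrees at every interface (the clinical
convention); conversion to radians happens internally.  The geometry
functions are total in $\theta$ (valgus, $\theta<0$, is computed
correctly), but the planning functions refuse negative angles because a
varus osteotomy is never planned in valgus.

# Radiographic measurements

All measurements run in a **canonical frame** derived from the pelvic
teardrop landmarks: the ipsilateral teardrop is the origin, the tear-drop
line is the x-axis, +x points laterally *for the hip under study*, +y
proximally.  The lateral direction is taken from the vector
`teardrop_contra → teardrop_ipsi`, so left-hip (mirror image) files land on
the same canonical coordinates as right-hip files and the `side` column is
pure metadata.  The transform is rigid (plus a mirror where needed), so
every derived quantity is invariant to the raw digitization frame — a
property the tests verify directly with random rotations, translations and
mirrorings.

* **Neck-shaft angle (NSA)**: the angle between the neck axis (digitized
  toward the head) and the shaft axis (digitized toward the knee); varus
  angulation is $\theta = \mathrm{NSA}_{pre} - \mathrm{NSA}_{post}$.
* **VD / LD**: vertical distance of the greater-trochanter tip from the
  tear-drop line, and lateral distance of the lateral trochanteric border
  from the teardrop reference.  In the canonical frame these are coordinate
  read-offs.  Actual shortening is $VD_{post} - VD_{pre}$; actual
  lateralization is $LD_{post} - LD_{pre}$.  The horizontal origin of LD is
  not standardized in radiographic practice; we use the ipsilateral
  teardrop point.  Since only pre/post *differences* enter any downstream
  quantity, this choice is inconsequential as long as it is consistent.
* **Head and arc centers**: circle fits of the three digitized head-rim
  points and of the $k \ge 3$ points digitized along the osteotomy arc.
* **Lateral head index (LHI)**: $100 \times$ intact lateral width / full
  head width, with widths measured as horizontal extents (parallel to the
  tear-drop line) between `head_medial`, `head_lateral` and the
  `necrosis_lateral_margin` landmark, clamped into $[0, 100]$.  An absent
  margin means a fully intact head.  Delineating the necrotic area itself
  (an MRI task) is out of scope; the margin is an input landmark.

**A subtlety with post-operatively measured offsets.**  Head and arc
centers are measured on the post-operative film, where the head sits at
$H' = R(\theta)(-A, B)$ relative to the arc center — the *rotated* offset
pair, not the planning pair $(A, B)$.  `measure_hip()` therefore de-rotates
the measured head-to-arc vector by the measured $\theta$ before reporting
$A$ and $B$.  This is the operational meaning of the observation that the
relation between the distal fragment and the arc center does not change
with surgery.  At zero digitization noise the de-rotation recovers the
generator's ground truth exactly (verified to $10^{-6}$ mm in the tests).
When arc points are also digitized pre-operatively, the distance between
the directly fitted pre-operative arc center and the position implied by
the post-operative fit is reported as `arc_center_discrepancy`, a useful
per-hip quality flag.

The greater trochanter is treated as part of the distal fragment (CVO is
specifically credited with avoiding trochanteric elevation), so VD/LD track
the distal fragment's translation — exactly the displacement that defines
leg-length change.

# Inverse planning

* `max_lateral_shift(B, theta, s_max)` inverts $s(\theta)$ in $A$:
  $A_{max} = (s_{max} - B(1-\cos\theta))/\sin\theta$.  The default budget
  $s_{max} = 5$ mm is the usual threshold for a clinically relevant
  discrepancy.
* `shortening_sensitivity()` gives the analytic partials
  $(\sin\theta,\; 1-\cos\theta,\; (A\cos\theta + B\sin\theta)\pi/180)$ —
  handy for error budgeting: at $\theta \approx 22^\circ$ a millimetre of
  error in $A$ moves the prediction by only $0.37$ mm, and a degree of
  error in $\theta$ by about $0.11$ mm at typical offsets.
* `required_varus_for_lhi()` searches for the smallest $\theta$ whose
  post-rotation LHI reaches the indication threshold (default 25%).  The
  post-rotation LHI is a geometric operationalization — rotate the head
  borders and necrosis margin about the arc center, re-measure the
  horizontal extents — not a formula inherited from radiographic practice,
  where the post-operative LHI is simply re-measured on the new film.  The
  profile is evaluated on a $0.5^\circ$ grid over $[0^\circ, 45^\circ]$;
  if it is monotone non-decreasing (the generic case: varus rotates the
  intact lateral region into the weight-bearing zone) the crossing is
  refined by bisection to $0.005^\circ$; a non-monotone profile falls back
  to the smallest feasible grid angle with a warning.  The $45^\circ$ cap
  sits safely above the clinically used range (15–38°), and answers outside
  that range raise a warning rather than an error.

# Validation statistics

`pearson_cor()` wraps the product-moment correlation with the two-sided
t-transform p-value.  `icc()` computes single-measure intraclass
correlations from one- or two-way ANOVA mean squares (`stats::aov`).
Radiology papers rarely state which ICC form they used, so the form is an
explicit argument and is echoed in every result: the package defaults to
ICC(2,1) (two-way random, absolute agreement) for inter-rater work and
recommends ICC(1,1) (one-way random) for intra-rater repeats; ICC(3,1)
(consistency) is available for completeness.  Tables must be complete — no
imputation is attempted.  No multiple-testing correction is applied to the
four validation correlations; they are reported with full-precision
p-values and the reader applies whatever threshold they favor.

`validate_cohort()` bundles the four standard relationships — predicted vs
actual shortening, predicted vs actual lateralization, varus angle vs
shortening, lateral shift vs shortening — plus the per-hip scatter data and
a cohort summary with the share of hips at or above the 5 mm threshold.
Degenerate inputs (e.g. a constant-$\theta$ cohort) flag the affected
correlation as undefined instead of failing the run.

# The synthetic-cohort generator

No public landmark dataset exists for this procedure, so `simulate_cohort()`
is a first-class module: it draws ground-truth geometry, renders landmark
files, and the rest of the package never touches the truth except through
those files.

Sampling defaults reflect reported clinical cohorts for this procedure: $n = 42$ hips;
$A \sim \mathrm{TN}(3.3, 5^2)$ on $[-8, 21]$ mm;
$B \sim \mathrm{TN}(9.3, 4^2)$ on $[1, 21]$ mm;
$\theta \sim \mathrm{TN}(21.7, 5^2)$ on $[15, 38]^\circ$.  Reported
clinical values are typically means and ranges only; the truncated-normal
family and its standard deviations are generator choices (a uniform-over-range family is
available as an option).  Note that asymmetric truncation shifts the
distribution's expectation slightly away from the center parameter
(≈ +0.9° for $\theta$); the tests compare sample means against the exact
truncated-normal expectation.

The rendered scene uses fixed, anatomically plausible adult AP-radiograph
geometry: inter-teardrop distance 115 mm, head center 32 mm lateral and
58 mm proximal to the ipsilateral teardrop, head radius 25 mm, arc radius
22.5 mm (the middle of the 40/45/50 mm cutting-guide diameters),
pre-operative NSA 135°, necrotic fraction of the head width uniform on
[0.6, 0.95].  Post-operative scenes rotate the proximal-fragment landmarks
about the arc center by $\theta$ and then translate all femoral landmarks
so the head center returns to its acetabular position — the clinical frame,
in which VD/LD are meaningful.  Each radiograph then gets its own random
raw frame (rotation ±8°, translation ±15 mm, x-mirror for left hips) and
independent Gaussian noise of `noise_sd` (default 0.5 mm, a typical manual
digitization error) on every coordinate.  `noise_sd = 0` is fully supported
and gives exact round trips.

What the generator does **not** emulate: hip adduction/abduction or
rotation differences between films (a recognized source of error in LD
measurements), fragment translation at the cut, nonunion or remodeling,
magnification miscalibration, and anatomical variation of the scene
constants across patients.  Passing tests therefore demonstrate internal
consistency of model + measurement + statistics under controlled noise, not
performance on real radiographs.

## What correlation can be expected at the default noise level

A useful back-of-envelope: actual shortening is a difference of two VD
measurements, each involving the trochanter-tip y-coordinate and the
teardrop frame, so roughly four independent noisy coordinates (plus a small
tear-drop-line slope term) enter it; at 0.5 mm per coordinate that is an
irreducible ≈ 1.0–1.15 mm of noise.  The sampled cohort's true shortening
has a spread of only ≈ 1.9 mm, so even a noise-free prediction cannot
correlate with the measured shortening above
$1/\sqrt{1 + (1.05/1.9)^2} \approx 0.88$; in practice the predicted value
carries some noise too and the correlation at the default settings is
typically 0.75–0.88.  Real cohorts with a wider spread of shortening (a
range of −5 to +11 mm implies a standard deviation near 3 mm) support
correlations above 0.9 at the same measurement noise.  The acceptance
suite states the stronger across-seed property and records its outcome;
the module tests assert the properties that are robustly true (exact
recovery at zero noise, strong positive correlation at the default noise,
degradation with increasing noise).

## Problem sizes

The shipped tests and the acceptance script use a typical single-center
cohort size (42 hips), 100 seeded replicates for across-seed
stability, 10⁴ random parameter triples for the oracle-equivalence check,
200 fits per noise level for the circle-fit convergence check, and a
10⁴-hip draw for the sampling-distribution check — all chosen to keep the
full run in the low minutes on a single CPU while leaving Monte-Carlo
error well below the asserted margins.

# Numerical choices

* **Circle fitting** uses the algebraic (Kåsa) least-squares formulation,
  solved about the centroid for conditioning: closed-form, deterministic,
  exact for 3 non-collinear points (the circumcircle) and adequate at
  landmark-scale noise; no iterative geometric refinement is attempted.
  Collinearity is declared when the second singular value of the centered
  points falls below $10^{-9}$ of the first, and raises a
  degenerate-geometry error.
* **Canonical frame orientation** resolves the y-sign by requiring the
  trochanter tip above the tear-drop line (falling back to the landmark
  centroid in the degenerate case); coincident teardrops raise an error.
* **Bisection tolerance** for the required-varus search is $0.005^\circ$,
  an order of magnitude below anything clinically meaningful.
* **Exactness tolerances** in the tests are $10^{-9}$ mm for pure geometry
  and $10^{-6}$ mm/degree for full pipeline round trips (the looser value
  absorbs the conditioning of circle fits and frame changes).

# Limitations

The model is planar and rigid; out-of-plane rotation maps poorly onto a
single AP film, and the weak lateralization agreement seen clinically
(attributed to adduction/abduction positioning) is *not* reproduced by the
generator, whose lateralization correlations are optimistic.  The
post-rotation LHI is a geometric surrogate; it ignores the fact that the
weight-bearing sourcil does not rotate with the femur.  The ICC defaults
are reasonable conventions, not a claim about how any particular published
agreement figure was computed.
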