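---
title: "Morphometry and in silico haemodynamics of the left atrial appendage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry and in silico haemodynamics of the left atrial appendage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laametrics)
```

# The problem

The left atrial appendage (LAA) is a blind-ended pouch of the left atrium
and the dominant site of thrombus formation in nonvalvular atrial
fibrillation. Following Virchow's triad, both the *shape* of the pouch
(a larger, longer, more wound appendage retains more blood) and the
*flow* inside it (low, oscillatory wall shear and poor washout mark
stagnation-prone walls) plausibly contribute to risk, yet neither family
of measurements separates TIA/CVA patients from controls on its own.
`laametrics` implements the complete joint pipeline: mesh-based
morphometry, wall-shear-stress (WSS) index post-processing, a washout
model of stagnation, the two-group statistics, and a synthetic cohort
generator calibrated to published group distributions so that every stage
is testable end to end.

# Morphometry

## Reference frame

All indices are computed in a common frame: the least-squares plane of
the ostium rim is rotated onto the zx-plane with the appendage body on
the +y side, the rim centroid (the LAA origin) moves to the origin, and
the maximum-diameter direction of the rim is rotated onto the x-axis.
Every downstream feature is invariant (to well below 0.1%) under any
rigid transform applied before the pipeline; the test suite checks this
property directly.

## Ostium metrics

`D_max` is the maximum pairwise distance between rim points; `D_min` is
the minimal rotating-caliper width of the rim projected into its plane
(the minimum over convex-hull edge directions of the projection width).
The caliper definition matters: the minimum centroid-to-rim radius is a
*separate*, smaller quantity (`r_min`), as the published group means make
plain (a printed mean minimum radius of 6.99 mm against half a printed
minimum diameter of 8.73 mm), so the two are implemented independently.
Eccentricity is `1 - D_min/D_max`. Area and perimeter come from the
projected rim polygon. One published consistency wrinkle: applying the
eccentricity formula to the printed TIA/CVA mean diameters gives 0.35
where the table prints 0.34 ± 0.08 — a rounding artefact of the printed
table; the tests therefore check this reproduction to ±0.01.

## Centreline

The published pipeline delegated centreline extraction to external
software whose algorithm is not described, so this package implements a
reproducible alternative: perpendicular-section marching. Starting at
the rim centroid and heading along the inward rim-plane normal, the mesh
is sliced one step ahead with the plane orthogonal to the current
direction; the area centroid of the nearest closed intersection contour
becomes the next centreline point. Several details carry the robustness:

- slices are taken against the *capped* surface, since an open ostium
  would let tilted cuts escape through the rim as low-area open contours;
- contour centroids are **polygon area centroids over the chain-ordered
  contour** — crossing points are not uniformly spaced around the contour
  (a plain point mean is biased by the mesh's diagonal direction), and
  contours at tight bends are crescents that defeat angle-sorting;
- a **predictor–corrector** step re-slices at the tentative centroid with
  the updated normal, so stored points are perpendicular-section centroids;
- the direction update is **damped adaptively against taper**: a tilted
  cut of a tapering tube biases its centroid sideways with gain
  `~ r |dr/ds| / step`, which makes an undamped march oscillate; the
  damping factor is chosen each step so the closed-loop gain stays below
  0.6 (`step` defaults to 2 mm);
- when a slice plane wraps around a strong bend and merges both limbs
  into one contour, the *local sub-loop* (the chain-ordered run of
  crossing points near the target, closed by its end chord) is rescued;
- marching stops at the tip dome (when little wall remains ahead within a
  lateral corridor of the axis — the corridor excludes a distal limb
  curling back past a bend) or when the section radius falls below 1 mm;
  the thin tail is then finished by binning the remaining wall vertices
  along the tail's own principal axis, with an epsilon in the binning so
  that a vertex ring lying exactly on a bin boundary stays in one bin.

The path is lightly smoothed (window 3) and resampled at 0.5 mm. Length
is the polyline arc length; tortuosity the chord-to-arc ratio (≤ 1,
lower = more winding — the convention under which the published medians
of 0.77–0.79 make sense); the bending angle is measured between the
arc-length-weighted mean tangents of the proximal and distal thirds,
with 180° meaning no bend.

On analytic fixtures the pipeline recovers a 40 mm straight cylinder to
±0.8 mm with tortuosity 1.00, and a quarter-torus tube to within 0.1% of
its analytic arc length. On the synthetic cohort it recovers generator
ground truth within 3% for about five of six subjects; the residual
errors concentrate in hairpin realizations near the published tortuosity
minimum (0.45), where the constant-curvature centreline turns through
~230° and the inner walls of the two limbs almost touch — a regime in
which any mesh-based centreline is ill-conditioned. This limitation is
deliberate: the generator draws those shapes because the published range
includes them, and softening the generator to avoid them would have
changed the study conditions.

## Volume, extents, regions

Volume is computed by signed tetrahedra over the watertight mesh after
fan-capping the ostium from the rim centroid, and reported in ml; wall
area excludes the cap. The neck height is the perpendicular extent above
the ostium plane and the distal point length the maximum distance from
the LAA origin — the figure defining them in the source names but does
not construct them, so both are documented interpretations. Anterior and
posterior distances are measured along x from the volume centre of mass,
and their sum is the anterior–posterior distance by construction. The
regional partition cuts the centreline at one- and two-thirds arc length
and labels every wall vertex by its nearest centreline third (inferior =
closest to the ostium).

# Haemodynamic indices

Per node and per beat window (default beats 2–3; the first simulated beat
is a stabilisation transient and is excluded),

$$\mathrm{TAWSS} = \frac{1}{T}\int\|\tau\|\,dt,\qquad
  \mathrm{OSI} = \frac12\Bigl(1 -
  \frac{\|\int\tau\,dt\|}{\int\|\tau\|\,dt}\Bigr),\qquad
  \mathrm{ECAP} = \frac{\mathrm{OSI}}{\mathrm{TAWSS}},\qquad
  \mathrm{RRT} = \bigl[(1-2\,\mathrm{OSI})\,\mathrm{TAWSS}\bigr]^{-1},$$

with trapezoidal time integration. The OSI and RRT formulas as printed in
the source are typographically garbled; the standard definitions above
are used, consistent with ECAP = OSI/TAWSS and the WSS literature. OSI
lies in [0, 0.5] by the triangle inequality; RRT is capped (default
10³ s) at fully oscillatory or zero-shear nodes and capped nodes are
counted; zero-shear nodes get TAWSS = 0, OSI = 0 and missing ECAP/RRT.
Aggregation discards values outside the P10–P90 band
(linear-interpolation percentiles) and averages the rest, unweighted over
nodes — the source does not state a weighting, and an area-weighted
variant would be a one-line change in `trimmed_aggregate()`. Trimming
operates on the pooled per-node value distribution, since the indices are
per-node scalars.

Blood-flow velocity inside the LAA is summarised as the volume-weighted
mean speed over the sample points and beat window, divided by the LAA
volume (units (m/s)/ml; the source prints two different unit strings for
this quantity in different tables, an inconsistency recorded here rather
than resolved). Stagnation integrates the positive part of the ostium
flow-rate trace to an outflow volume per beat and compares it with the
LAA volume; the default perfect-mixing model reports
`100·exp(-V_out/V)` percent of blood not renewed, and a piston
alternative (`100·max(0, 1 - V_out/V)`) is provided. The source states
only that stagnation was assessed "by integrating the flow rate at the
ostium"; perfect mixing is the physically conservative reading and the
default.

# The synthetic cohort generator

The generator exists because the study's images, meshes and CFD fields
are not public: it emits meshes, wall-field series, flow traces and
ground truth with the statistical structure the analysis assumes, so the
pipeline can be validated by parameter recovery and exercised at the
published group sizes (38 controls, 33 cases).

**Draws.** Per-group marginals follow the published rows: normal
mean ± SD for the ostium diameters, centreline length and bending angle;
log-normal matched to median (min–max) for LAA/LA volume (the range is
mapped to ±2.2 SD on the log scale, the expected extremes of a sample of
~38); logit-normal for tortuosity. The two ostium diameters correlate at
0.7 and each correlates with LAA volume at 0.4 through a Gaussian copula
(anatomically sized features co-vary; the exact values are a modelling
choice surfaced in `synthetic_spec()`). Normal margins truncate at ±3 SD
by redrawing the subject, as do infeasible combinations (minimum diameter
crowding the maximum, or a bend too tight for the tube radius); redraw
counts are recorded.

**Meshes.** Each subject is an elliptical cross-section (the drawn
ostium diameters) swept along a constant-curvature planar arc whose total
turn is solved from the drawn tortuosity (chord/arc of an arc is
sinc(θ/2)); arc length equals the drawn centreline length; the section
tapers as `(1-u²)^(γ/2)` with γ solved so the swept volume matches the
drawn LAA volume (γ clamped to [0.35, 6]; the realized volume is recorded
as ground truth). The ellipse's major axis is kept perpendicular to the
bending plane so the bending-plane tube radius is the minor axis, which
keeps the sweep embeddable down to the published tortuosity minimum. Two
consequences are deliberate: the *drawn* bending angle cannot also be
realized (a planar curve cannot match the published tortuosity and
bending distributions simultaneously without self-intersecting tubes), so
bending emerges from the arc as `180° - 2θ/3` and is recorded in ground
truth; and at extreme draw combinations the taper clamp means the
realized volume deviates from the nominal draw — all downstream stages
use measured values, so this only widens the realized volume
distribution's centre. Every generated mesh is watertight once capped,
carries its rim explicitly, and receives a random rigid pose (stored) so
that alignment is genuinely exercised.

**Fields.** Per wall node at arc position `s`, the WSS vector is
`τ₀·w(t)·[cos ψ ê₁ + sin ψ sin(2πt/P) ê₂]` with `ê₁` the local tangent
and `ê₂` circumferential. The angle ψ is solved per node (on the actual
time grid) so the discrete OSI hits its target — a profile declining
mildly from ostium to tip whose node mean equals the subject's OSI draw.
The pulsatile envelope `w(t) = 1 + 0.35·cos(4πt/P)` is orthogonal to the
reversing harmonic over whole beats, so it perturbs neither index. The
magnitude profile decays as `exp(-s/λ)` with λ = L/2 (velocities decrease
from ostium to tip), carries a mild side-to-side variation (walls are not
axisymmetric — and distinct per-node values also keep percentile-trim
boundaries off the ring-wise ties a swept mesh would otherwise produce),
and its scale is solved in closed form so the trimmed-mean ECAP equals
the subject's ECAP draw. The five published whole-LAA index rows cannot
all be calibration anchors at once: ratio identities do not survive
averaging (the printed group RRT of ~10 s is more than twice the value
the identity would give from the printed mean OSI and TAWSS), so the
anchors are OSI, ECAP, the volume-normalised velocity and the stagnation
percentage, while TAWSS and RRT levels emerge. The emergent RRT group
means land close to the printed ones; the emergent TAWSS ordering
reverses a published (far from significant) ordering, which no asserted
trend depends on. Beat 1 carries a quadratic amplitude ramp so that
including it in the averaging window biases the indices measurably — a
deliberate check that the beat-2–3 window logic matters. The ostium
trace is a signed sinusoid whose per-beat outflow inverts the mixing
washout at the subject's stagnation target, and velocity samples decay
along the centreline with weights summing to the LAA volume, scaled so
the velocity index equals its target exactly.

**Stagnation spread.** The source reports only group mean stagnation
percentages; the generator draws per-subject values from a moment-matched
log-normal with an SD of 6 percentage points, a realistic washout spread
chosen once and documented here.

# Statistics

Continuous features pass a per-group Shapiro–Wilk gate at 0.05: if both
groups are compatible with normality the groups are compared with a
pooled-variance two-sided t-test (Welch behind a flag), otherwise with a
two-sided Mann-Whitney test (normal approximation with tie correction
beyond n = 20). Categorical features use chi-squared without continuity
correction; on the published gender 2×2 the uncorrected statistic is 5.93
(p = 0.0149) against a printed 0.019 that matches neither the corrected
nor the uncorrected variant — both are exposed. Reporting follows the
mean ± SD / median (min–max) / count (%) convention according to the
gate's outcome. No multiple-testing correction is applied by default
(matching the per-test α = 0.05 design); Benjamini–Hochberg is available
via an argument.

The stepwise logistic model is binomial-logit, searched bidirectionally
by AIC from the full candidate model (the source does not state the start
point; starting full lets correlated candidates compete immediately).
`joint_model_comparison()` fits morphology-only and
morphology-plus-haemodynamics candidate sets on the same subjects and
reports both AICs; on the default synthetic cohort the joint model
improves the AIC, the qualitative analogue of the published comparison.
Whether the published model was logistic is not stated ("regression
model" on a binary outcome); logistic is assumed. The random forest uses
the published hyperparameters (500 trees, 4 variables per split, at most
90 terminal nodes) with Gini importances; accuracy is out-of-bag, since
the published accuracy protocol is unstated. Perfect separation in the
logistic model is reported with a flag rather than interpreted.

# Problem sizes and numerical choices

The default mesh resolution is 48 vertices per ring at ~1.25 mm axial
spacing (≈ 1300–2000 vertices per subject) — comfortably finer than the
0.5 mm feature scale of the geometry while keeping a full 71-subject
cohort (meshes, fields, measurement) around half a minute; halving the
edge length changes volume, area and centreline length by well under 1%.
Synthetic series use 40 timesteps per beat over 3 beats of 1 s. The
trimmed mean requires ≥ 10 values per region; the RRT cap defaults to
10³ s; percentiles are linear-interpolation (type 7). Statistical
simulations in the test suite use 2000 replicates for error rates, which
bounds the Monte-Carlo SE of a 5% rate at about 0.5 percentage points.

# What passing tests do and do not show

The generator emulates the *statistical* structure of the study —
per-group feature distributions, within-LAA gradients, effect directions
— not patient-specific physics: cross-sections are elliptical, the
centreline is a single planar arc, wall fields follow a closed-form
profile rather than a Navier–Stokes solution, and boundary conditions,
mitral annulus motion and vortex structure are out of scope. Parameter
recovery therefore validates the measurement pipeline, not the realism of
any individual synthetic patient. Cohort-level conclusions (group means,
medians, effect directions, the morphology-versus-joint AIC comparison)
are the quantities the synthetic study design supports; published
patient-level results (a specific joint-model AIC of 14, a specific 70%
accuracy) derive from 71 real patients and 30 CFD simulations that are
not reproducible at desk scale.

# Known limitations

- Centreline recovery degrades on hairpin-bend realizations near the
  published tortuosity minimum (see above); worst-case length error on
  the seeded cohort is ~18% for such subjects while the cohort mean is
  recovered to 0.1%.
- The "LAA width" mentioned in the source's results narrative has no
  stated definition and is not computed; the LAA shape label
  (chicken-wing versus not) is carried as metadata, never inferred from
  geometry, matching its expert-label provenance and high interobserver
  variability.
- Binary mesh formats are not read; STL/PLY/VTK are supported as ASCII.
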