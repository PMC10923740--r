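---
title: "Methods: 3D HTO planning, execution and evaluation in hto3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D HTO planning, execution and evaluation in hto3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hto3d)
```

# The measurement model

All computations run on a triangulated bone surface (mm) plus twelve named
anatomical landmarks. The anatomic frame is defined by the tibial plateau:
the y-axis runs posterior→anterior along the medial plateau line
(TMCP→TMCA), the xy-plane additionally contains the proximal joint line
direction (MMPP→MLPP), the z-axis is the plane normal oriented proximally,
and the x-axis completes a right-handed frame; the origin is the tibial
knee center (TKC). Because the five defining landmarks are coplanar on the
plateau, "proximally" cannot be inferred from them alone; the declared side
of the specimen resolves the normal's sign, which also fixes the x-axis
convention (lateral for a right tibia, medial for a left one). All reported
angles are side-normalized, so mirror-image specimens yield identical
values.

The anatomical shaft axis passes through the area centroids of the two
cross-sections at one and two thirds of the shaft length, with shaft length
measured along frame z from the plateau landmark level to the distal-most
vertex. Cross-sections are extracted as mesh–plane intersection contours;
the largest closed contour wins (distal slices can clip the malleolus
bump), and an open contour falls back to the polyline vertex centroid with
a warning.

Angle definitions, with the projection planes made explicit since each
angle should be a single-plane quantity:

* **MPTA** — the medial-side angle between the joint line (MMPP→MLPP) and
  the proximally directed shaft axis, both projected into the frame's
  coronal (x–z) plane. Range (45°, 135°); ~87° is normal.
* **Slope** (medial/lateral) — 90° minus the 3D angle between the
  posterior→anterior plateau line (TMCP→TMCA or TLCP→TLCA) and the shaft
  axis; positive when the plateau dips posteriorly-distally. Measured
  against the 3D axis rather than its sagittal projection — a deliberate
  choice that keeps both slopes consistent with a single axis estimate.
* **Torsion** — the angle between the dorsal plateau tangent (PMC→PLC) and
  the distal reference line (IFT→MMAL), both projected into the frame's
  axial (x–y) plane, folded to the line-to-line range (−90°, 90°], external
  rotation positive.

# The virtual osteotomy

The biplanar plan consists of:

* an **ascending (coronal) cut** with normal = frame y, 10 mm posterior of
  the most ventral tuberosity point (TTV). An unbounded coronal plane 10 mm
  behind TTV would also pass through the anterior plateau rim of any
  realistically proportioned tibia, so the cut is bounded above at
  z(TTV) + 20 mm; bone anterior of the plane but above this level remains
  proximal. In reality the saw exits the anterior cortex above the
  tuberosity — the bound models that exit level.
* a **main cut** through the medial entry point — the medial cortex point
  half a maximum-plateau-width (W/2, W = |MMPP−MLPP|) distal to the medial
  plateau — containing the medial slope direction (TMCA→TMCP) and aiming at
  the point 15 mm distal (frame z) to the lateral plateau. Its in-bone
  extent terminates 15 mm medial of the lateral cortex; the cortex exit
  point of the in-plane medial→lateral ray is the **hinge**.

The opening angle about the hinge axis (frame y through the hinge point) is
solved by bisection so that the most medial cut-contour point displaces by
the gap target along frame z (default 8 mm, "measured in the z direction" —
not the Euclidean gap); the solver tolerance is below 1e-6 mm and the angle
is constrained to (0°, 30°).

Fragment assignment: a point is distal iff it lies below the main cut, or
anterior of the ascending cut and below its upper bound (the tuberosity
flange travels with the shaft). The distal fragment rotates rigidly; the
proximal fragment, on which the plan-vs-result registration is later
anchored, stays fixed, so execution errors appear distally in the deviation
maps. The 15 mm lateral bridge cannot simultaneously stay intact and allow
a rigid rotation; the virtual model treats it as cut through (no plastic
hinge deformation is modeled) — a recorded idealization. Cut faces are left
open (uncapped): the gap is measured between cut-contour points, so
watertight capping is unnecessary. Similarly, the full main-cut plane
separates the tuberosity flange from the shaft before both move together;
plan and realized surfaces share this convention, so it cancels in the
evaluation.

A small residual torsion change of ≈0.19° at the default 8 mm opening is
intrinsic to the constructs: rotating the distal fragment by the opening
angle θ about the frame y-axis scales the x-components of the distal
reference line by cos θ before the axial projection, shifting the projected
line angle by atan(tan τ / cos θ) − τ (τ = torsion). This is a property of
the measurement definitions, not an implementation artifact, and stays
below the 0.2° planning budget for realistic opening angles (θ ≲ 7°).

# Plan-vs-result evaluation

The realized anatomy is registered to the planned one with point-to-surface
ICP (Kabsch updates on deterministic vertex subsamples, closest points via
an exact C++ triangle kernel), initialized from the best of several
centroid/principal-axes pre-alignments and iterated until the RMS
improvement drops below 1e-6 mm (default cap 100 iterations, with a warning
and a flagged transform on non-convergence). Registration uses only the
proximal region — by default the crop 60 mm below the plateau, a parameter
since only "the proximal part" is reproducible between plan and result —
and the estimated transform is then applied to the entire realized mesh.

Each realized vertex receives the signed perpendicular distance to its
closest point on the planned surface, signed by the planned face's outward
normal (positive = outside the plan). Absolute deviations are binned into
half-open tolerance bands [0, 0.6), [0.6, 1.2), [1.2, 1.7), [1.7, ∞) mm
(very good / good / acceptable / unacceptable). The specimen grade is the
band containing the 95th percentile of |d| — a package decision: the
qualitative per-specimen labels in published series come without a stated
numeric rule, and the 95th percentile is insensitive to isolated
segmentation spikes while still penalizing genuine under-correction.
Per-specimen angle deviations are absolute differences (2 decimals);
cohort summaries report the arithmetic mean of absolute deviations and the
sample SD (n−1).

# The synthetic tibia

`generate_tibia()` builds a stylized phantom: a tapered elliptical shaft
(half-axes 1.15 r × 0.95 r, 15 % linear distal taper), a metaphyseal flare
over the proximal 30 % of the length chosen so the medial cortex at the
entry level sits at a realistic offset (and hence the planning lever and
opening angle match real tibiae), a distal flare with a medial malleolus
bump and a fibular-notch indentation, an anterior tuberosity bump at
z = −0.125 L, and a plateau surface z(x, y) = tan α·x + tan σ(x)·y whose
per-side slopes σ blend smoothly across a narrow central strip.

Two couplings are inverted numerically so that the *measured* angles equal
the targets exactly: the joint-line tilt α (the frame's y-axis is itself
tilted by the medial slope, which perturbs the coronal projection) and the
distal twist ψ (solved so the torsion measured through the full frame
equals the target). Additionally the IFT feature level is solved so the
distal reference line is parallel to the plateau plane; anatomically the
fibular notch sits just proximal to the malleolus tip, and this choice
decouples torsion from coronal rotations (see the residual above). Slopes
need no inversion — the plateau lines realize them exactly against the true
shaft axis. Landmark coordinates are emitted from the same closed-form
surface function that generates the mesh: feature landmarks are mesh
vertices (bump centers snap onto mesh rings; the circumferential resolution
is rounded to a multiple of 8 so the feature angles are sampled), plateau
landmarks lie on planar facets of the cap, and the IFT landmark sits on the
analytic surface within the triangulation's interpolation error (≈0.1 mm at
the default resolution).

Default study conditions: length 360 mm, plateau 75 × 50 mm, shaft radius
13 mm, MPTA 87°, slopes 8°/7°, torsion 35°, resolution 48 × 120
(≈6 200 vertices), gap target 8 mm — one specimen generates in ≈1 s and a
13-specimen cohort evaluates in ≈1–2 min on one CPU; tests use a 32 × 80
resolution where many phantoms are needed (a 3×3×3 recovery grid), which
changes measured angles by < 0.05° relative to doubled resolution.

What the phantom does **not** emulate: condylar concavity and asymmetry,
cortical thickness (the model is a surface), the fibula, soft tissue, and
CT segmentation noise. Passing tests therefore demonstrate internal
consistency of the geometry pipeline — parameter recovery, invariances,
exact oracles — not anatomical realism of any single measurement on
clinical data.

## Error models

Surgical execution error has three interpretable knobs: a multiplicative
shortfall of the opening angle (general under-correction, e.g. wedge
settling), an axial tilt of the hinge axis (which provably couples the
coronal correction into the slope — a 20° posterolateral tilt changes the
slope by > 2°), and an extra closure of the anterior gap (ventral
under-correction from posteriorly seated wedges), implemented as a small
extra rotation about the in-plane medial–lateral axis solved for the
requested anterior closure. Observer variability is isotropic Gaussian
landmark jitter; under equal jitter, torsion is the least reliable angle
because its defining landmarks span the shortest levers — reproducing the
reliability ordering reported for manual 3D measurements (torsion ICC far
below the other angles).

The synthetic cohort in `run_pipeline()` draws per-specimen anatomies
(MPTA ~ N(87, 2°), slopes ~ N(8, 2°)/N(7, 2°), torsion ~ N(35, 5°), clipped
to feasible ranges) and execution errors from a bimodal quality mixture —
with probability 0.55 a near-ideal execution (scale ~ N(1, 0.006)),
otherwise an under-correction (scale ~ N(0.94, 0.025)), hinge tilt
~ N(0, 2°), occasional ≈1 mm anterior sag, landmark σ = 1 mm. These values
were fixed once to emulate the qualitative outcome mix reported for cadaver
series (roughly half the specimens very good/good, the rest
under-corrected) and are not fitted to any numeric target.

# Numerical choices and edge cases

* Duplicate-vertex merging at 1e-6 mm (STL is a triangle soup); degenerate
  (zero-area) faces dropped at construction; meshes need ≥ 4 vertices.
* Binary STL stores float32: a 360 mm bone round-trips to within the
  half-ulp 1.6e-5 mm; ASCII STL and PLY are written with 9 significant
  digits and round-trip to < 1e-5 mm.
* Frame construction rejects coincident or near-collinear (< 1°) defining
  landmarks; angle projections reject collapse below 1e-6 of the vector
  length.
* Mesh–plane sectioning nudges exactly-on-plane vertices by 1e-12 mm to
  avoid degenerate crossings; contour chaining is exact because
  intersection points are shared through canonical edge keys.
* The opening-angle bisection brackets (0°, 30°) and errors when the gap is
  unreachable (hinge too close to the medial point); landmarks within
  0.5 mm of a cut plane are assigned by sign with an ambiguity warning.
* ICP convergence is declared on an RMS improvement below `tol`; with
  partial overlap the point-to-point RMS can keep creeping, so the
  transform is still returned (flagged) when the cap is hit — recovery
  accuracy in the flagged cases is still ~1e-3° in the test conditions.
* Grading percentiles use linear interpolation (R quantile type 7).

# Known limitations

* The evaluation registers on a 60 mm proximal crop; large execution errors
  leak a small bias into the registration because part of the cropped
  region belongs to the (moved) distal fragment. The null test is
  unaffected; cohort deviation maps inherit a bias well below the band
  width for the error magnitudes modeled.
* The deviation sign uses the closest face's normal; for points equidistant
  to a sharp edge between opposed faces the sign can flip. Band
  classification uses |d| and is unaffected.
* The per-cohort angle-deviation magnitudes of the synthetic cohort depend
  on the chosen error model and are not calibrated to reproduce any
  specific published cohort's means; only the worked-example statistics
  recomputed from published per-specimen values are asserted numerically.
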