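---
title: "Simulating and scoring AR-guided cranial suture delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring AR-guided cranial suture delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In minimally invasive spring-assisted craniectomy for craniosynostosis, the
surgeon needs to localize cranial sutures (coronal, lambdoid, sagittal) on
the intact head to plan incisions. An augmented-reality navigation approach
tracks the patient and a pointer with an electromagnetic tracking system
(EMTS), aligns a CT-derived skull model to the patient by paired-point
registration of facial anatomical landmarks, and displays the planned
sutures on a head-mounted display so the surgeon can draw them on the skin.
The accuracy question is: *how far from the planned suture does the drawn
suture end up, and which error sources dominate?*

`suturenav` implements the computational core of that accuracy evaluation —
the transform chains, registrations, error metrics and scoring geometry —
plus a seeded synthetic phantom and study simulator, so the entire
evaluation pipeline runs and can be stress-tested with no tracking
hardware, no CT data, and no human participants.

## Rigid transforms and frame graphs

All geometry lives in millimetres in right-handed Cartesian frames; the CT
frame is defined by the skull mesh coordinates. A `rigid_transform` is a
proper rigid motion stored as a 4×4 homogeneous matrix (row-major in the
file format); construction enforces orthonormality and determinant +1 to
1e-9, so reflections and sheared matrices are rejected at the door.

A tracked AR system relates many frames — EMTS, the QR-marker sensor, the
QR marker, the display, the patient sensor, CT, and an optical tracker
(OTS) used for independent evaluation. `frame_graph()` stores calibrations
as directed edges and `resolve_frame_path()` composes the chain between any
two frames by breadth-first search, inverting edges traversed backwards.
When two distinct paths connect the same pair of frames, both are resolved
and compared on a unit probe; disagreement beyond 1e-6 mm raises an error
instead of silently picking one path — contradictory calibrations should
surface, not hide.

## Paired-point registration, FRE and TRE

Both the one-time tracker calibration (24 divot points on a marker plate)
and the per-session patient alignment (6 anatomical landmarks around the
nose and eyes) are paired-point rigid registrations, matched strictly by
label. `register_paired_points()` uses the closed-form orthogonal
Procrustes solution: SVD of the cross-covariance of the centered point
sets, with the determinant-sign correction that restricts the optimum to
proper rotations. No scaling, no iterative closest point: the physical
procedure pairs points explicitly.

Two error summaries follow the standard definitions:

* **FRE** (fiducial registration error) — RMS residual at the points used
  in the fit;
* **TRE** (target registration error) — RMS error at held-out targets
  (here the conical fiducial markers), the clinically relevant number.

`fre_tre_monte_carlo()` propagates isotropic Gaussian digitization noise
(sd σ per axis, applied to the measured side only) through the
registration. Its mean FRE² is testable against the first-order
approximation `E[FRE²] ≈ (1 − 2/N) · 3σ²`, and its per-target TRE exhibits
the lever-arm effect: with an anterior landmark cluster, error grows with
distance from the cluster, which is exactly why a posterior suture
(lambdoid) is localized worse than an anterior one (coronal).

## The delineation metric d = S_A / D_L

A drawn suture is scored against its planned counterpart by the mean gap
over the region where the two curves overlap:

* both curves are projected point-wise onto the skull surface and
  resampled at the planning resolution (0.25 mm);
* the reference is clipped to the arc interval between the closest
  reference points to the drawn curve's endpoints (and vice versa), giving
  the overlap length `D_L` measured along the clipped reference;
* the two clipped curves are resampled to a common point count at uniform
  normalized arc length, corresponded by index, and the ruled strip between
  them — each quad split along its shorter diagonal — gives the spanned
  area `S_A`;
* the reported distance is `d = S_A / D_L`.

For parallel planar segments at separation `h` with full overlap this is
exactly `h`; for a half-overlapping pair (reference spanning 0–100 mm,
drawn 50–150 mm at 3 mm separation) it gives `D_L = 50 mm`,
`S_A = 150 mm²`, `d = 3 mm`. The strip is a ruled surface in 3-D, not a
geodesic patch on the mesh; at millimetre separations on a
decimetre-radius vault the difference is second order, and the ruled strip
is well defined, convergent under step refinement, and exact in the plane.
`D_L` is measured along the clipped reference because the CT annotation is
the planning ground truth. Index correspondence (rather than closest-point
re-matching) avoids many-to-one pairings on curved strips.

## The synthetic phantom

`make_phantom()` builds a deterministic stand-in for a skull phantom:

* **surface** — the upper half of an ellipsoid with semi-axes
  70 × 55 × 50 mm (anterior–posterior × lateral × vertical), a child-skull
  scale, meshed as a latitude–longitude grid. Tessellation level `L` gives
  `6L` rings × `12L` sectors (level 4, the default, ≈ 4 500 triangles).
  The azimuth grid is offset by half a sector so the midline plane meets no
  ring vertex.
* **sutures** — plane sections of the mesh: the sagittal suture is the
  midline section; coronal and lambdoid are transverse sections at +0.35
  and −0.55 of the AP semi-axis; three "virtual" sutures sit at evenly
  spaced fractions in between. Section polylines have their vertices on
  mesh edges and every segment inside a facet, so they lie *exactly* on the
  surface and remain on it under arc-length resampling. They are stored
  unresampled; the 0.25 mm planning resample is applied where a curve is
  used.
* **landmarks** — six points clustered on the anterior face region at low
  elevation, mimicking landmarks around the nose and orbital rims; their
  deliberate anterior clustering reproduces the posterior error gradient of
  a real facial-landmark registration.
* **fiducials** — a configurable number (10 for an SK1-like adult layout,
  8 for an SK2-like child layout) placed by seeded stratified sampling over
  the vault: one per azimuth stratum with jittered elevation, snapped to
  the mesh.

Everything is a pure function of `(spec, seed)`.

### Noise channels

Three channels stand in for the study's physical error sources
(`noise_spec()`):

| channel | parameter | default | what it models |
|---|---|---|---|
| EMTS digitization | `emts_sigma` | 0.35 mm | pointer-tip noise during landmark digitization |
| OTS digitization | `ots_sigma` | 0.40 mm | optical-pointer noise during evaluation |
| delineation | `delineation_sigma`, correlation length | 1.0 mm, 15 mm | smooth wander of a human pen stroke |
| systematic offset | `systematic_offset` | 0 mm | constant sideways bias of the stroke |

The digitization defaults were derived by working typical phantom-study
registration errors backwards through the FRE approximation: an EMTS FRE
near 0.5 mm with N = 6 landmarks implies σ ≈ 0.35 mm, and an OTS FRE of
0.6–0.7 mm with N = 8–10 fiducials implies σ ≈ 0.4 mm. Human delineation
noise has no published magnitude, so it is a free parameter; 1 mm marginal
sd with a 15 mm correlation length is a plausible pen-stroke scale and is
deliberately *not* fitted to any observed aggregate. The delineation field
is correlated along the curve (a Gaussian field smoothed with a Gaussian
kernel over arc length, renormalized to unit marginal sd) because pen
strokes are smooth; independent per-point jitter at 0.25 mm spacing would
make the area strip pathological. Displacements act in the local surface
tangent plane and the result is re-projected onto the surface.

## The simulated study

`run_simulated_study()` replays the protocol per participant and phantom:

1. *experiment registration* — digitize the six landmarks in the EMTS
   frame with EMTS noise, register CT → EMTS, record FRE; record TRE at
   the (held-out) fiducials;
2. the imperfect alignment displaces the *displayed* sutures — the
   misalignment `T̂ ∘ T_true⁻¹` is applied to the planned curves, because
   the participant traces what the misaligned overlay shows;
3. *delineation* — simulate the drawn suture from the displayed one with
   the correlated hand-noise channel;
4. *evaluation registration* — digitize the fiducials with the OTS,
   register, record FRE;
5. digitize the drawn curves with OTS noise and map them into CT space
   through the evaluation registration;
6. score each drawn/planned pair with `delineation_distance()`.

The sagittal suture is displayed but never delineated (it serves only as a
midline guide), so 12 participants × 2 phantoms × 5 sutures = 120 records.
Per-participant sub-seeds derive from the master seed by a string hash
(`derive_seed()`), making every participant reproducible independently of
execution order. Registration is repeated per participant — the natural
reading of a reported FRE spread. A scoring failure from insufficient
overlap is recorded as a missing record with a warning, never a crash, and
missing counts appear in the run manifest. Summaries pool the virtual
sutures into one class and report mean ± sample sd (n − 1); a single-record
group reports sd 0 with `sd_defined = FALSE`.

```{r}
library(suturenav)
report <- run_simulated_study(study_config(seed = 1))
report$summary
report$registration_summary
```

## Numerical choices

* **Closest points** — exact point–triangle distance with face/edge/vertex
  classification, under a median-split AABB tree (compiled); ties between
  equidistant triangles break to the lowest triangle index so results are
  deterministic. An independent brute-force scan over all triangles backs
  the kernel in the tests.
* **Projection** is point-wise independent, like pointer digitization; a
  curve spanning a concave gap is projected point by point with no
  continuity constraint (a known limitation for pathological curves).
* **Resampling** interpolates linearly at uniform arc spacing, always
  keeping both endpoints (a curve shorter than one step collapses to its
  endpoints). It is *idempotent*: a curve whose chords already equal the
  step within 1 % is returned unchanged. Without this, re-resampling an
  already-uniform curve on a faceted surface lets sample positions drift
  onto corner-cutting chords; the error-free pipeline would bottom out at
  a few micrometres instead of being exact. Genuinely irregular curves
  vary far more than 1 % and take the normal path.
* **Zero-noise exactness** — with all sigmas zero the full chain
  (registration → display → drawing → evaluation → scoring) reproduces
  d ≈ 1e-10 mm and FRE/TRE ≈ 1e-13 mm; this is the pipeline's structural
  correctness check.
* **Degenerate inputs** — registrations require ≥ 3 non-collinear pairs
  with matching labels; meshes reject out-of-range indices and triangles
  below 1e-12 mm²; plane sections nudge the plane by 1e-6 mm if it passes
  exactly through a vertex; overlaps shorter than one resample step raise a
  no-overlap error.

## What the simulator does and does not show

The generator reproduces the *geometry* of the study — a convex vault with
an anterior landmark cluster, posterior targets, plane-section sutures —
and the *stochastic structure* of digitization and tracing noise. It does
not emulate anatomical suture shapes, CT segmentation artifacts, EM field
distortion, QR-marker occlusion (a visibly heavy-tailed error source in
practice), skin/foam thickness, or participant learning effects. Passing
tests therefore validate the algorithms and their implementation, not the
hardware system; absolute error levels in a real theatre depend on the
physical error sources the noise channels only approximate.

Problem sizes used in the test-suite: level-3/4 phantoms (≈ 2 300–4 500
triangles), 12–200 simulated participants depending on the property under
test, 10⁴ Monte-Carlo registration repetitions, 500-point closest-point
oracle scans — sizes at which the checked properties are already stable.

## Reproducing a full evaluation from files

The file interfaces mirror common planning tools: STL/PLY meshes, Slicer
FCSV or `label,x,y,z` CSV point sets (FCSV's RAS convention converted on
read), one CSV per suture curve, and plain-text 4×4 transform files. The
installed CLI (`system.file("cli/suturenav", package = "suturenav")`)
exposes `make-phantom`, `simulate-study`, `evaluate` (score externally
drawn curves against planned ones on a supplied mesh) and `report`.
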