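---
title: "Planning keyhole drill access to the semicircular canals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning keyhole drill access to the semicircular canals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(canalaccess)
```

## The planning problem

Vestibular implants stimulate the ampullary nerves of the three semicircular
canals (SCC). Placing their electrodes minimally invasively requires three
drilled keyhole tunnels from the mastoid surface, one per canal, each ending
in a small fenestration of the bony canal wall through which the electrode is
advanced towards the ampulla. A usable trajectory must

* keep a **safety margin** to critical structures (facial nerve, chorda
  tympani, external auditory canal, the other two canals, the lateral skull
  base, and the sigmoid sinus),
* meet the canal at a favourable **SCC entry angle** — the angle between the
  drill axis and the canal-centreline tangent at the fenestration site; 0°
  is tangential-anterograde, angles of 80° and above risk pushing the
  electrode retrograde, and
* originate, together with the other two trajectories, inside a single
  cortical **mastoidectomy** of 15 mm diameter that receives the excess
  electrode leads.

`canalaccess` implements this analysis as a pipeline from per-ear surface
meshes to per-case accessibility maps, fenestration-site sweeps, and a
mutually optimized three-trajectory plan, together with a seeded generator of
synthetic temporal-bone anatomy so every stage is testable without any
clinical data.

## Coordinate frame and inputs

All geometry lives in a right-ear frame with axes *(x lateral, y anterior,
z superior)*, origin at the inner-ear centre, units millimetres. Left ears
are mirrored about the sagittal plane through the inner-ear centre
(`normalize_side()`), with triangle winding re-flipped so outward normals
survive; the generator builds left ears as exact mirrors, so a left case and
its right twin produce identical metrics.

A case consists of closed triangular surface meshes for the three canals,
facial nerve, chorda tympani, external auditory canal (EAC) and temporal
bone, plus the sigmoid-sinus centreline, one nerve-stimulation target per
canal, an ear-canal reference point, and optionally a cochlear-implant (CI)
reference trajectory. `write_case()`/`read_case()` serialize a case as ASCII
STL + JSON landmarks + YAML parameters.

## The synthetic anatomy generator

`generate_case()` emulates the *geometric structure* the analysis relies on,
not human morphometry:

* **Canals** are torus-arc tubes (lumen diameter 1.1 mm, the midpoint of the
  anatomical 1.0–1.2 mm range; major radii 3.2–3.4 mm; 250° arcs) with an
  ellipsoidal ampullary widening at one end. The arc gap faces the
  vestibule; a per-canal gap rotation orients the ampullary arm so that the
  canonical access pattern emerges (lateral canal approachable nearly
  tangentially, posterior canal at low angles from posterior entry points,
  superior canal only steeply — its plane is roughly sagittal).
* **Nerves** are swept tubes (facial nerve radius 0.6 mm descending behind
  the middle ear, chorda tympani 0.25 mm branching anterosuperiorly).
* The **temporal bone** is an implicit solid — a medial block whose flat top
  models the middle-fossa plate and a lateral slab with a gently domed
  lateral surface — isosurfaced by marching tetrahedra. The sigmoid channel
  (radius 4 mm) and optional spherical air cells are carved from the
  interior, giving the outer-surface extraction real cavities to exclude.
* The **nerve targets** sit at the ampullary arc ends, within the ampulla.

Cohorts (`generate_cohort()`) draw per-case variation around this canonical
anatomy: ±10% isotropic scale, ±10° canal-orientation jitter, ±3 mm sigmoid
jitter (uniform distributions), and alternating left/right sides. All
randomness flows from one integer seed through per-case derived seeds, so a
cohort is bit-reproducible. What the generator does **not** emulate:
population morphometrics, air-cell pneumatization patterns, CT noise or
segmentation artefacts. Passing tests therefore demonstrate correctness of
the geometry processing, not clinical performance on real ears.

## Surface processing

* `crop_roi()` standardizes extent with a vertical triangular prism
  (equilateral footprint, 60 mm circumradius, centred 10 mm posterior of the
  inner-ear centre — dimensions are a package choice; any prism containing
  the mastoid works).
* `extract_outer_surface()` shrink-wraps the bone: an enclosing icosphere is
  alternately relaxed (damped uniform-Laplacian smoothing with an annealed
  step, 0.5·0.7^(k−1)) and projected onto the nearest point of the original
  mesh, until the maximum per-iteration displacement falls below 0.02 mm
  (cap 50 iterations), subdividing until the median face area is within 2×
  the 0.1 mm² target. Because projection proceeds from outside, interior
  cavities (air cells, the sigmoid channel) are excluded. The annealing
  makes the relax/project cycle contractive; without it the tangential drift
  plateaus near 0.1 mm.
* `extract_skull_base()` seeds from the first face hit by a superior ray
  from the inner-ear centre and floods over edge-connected, superior-facing
  faces (normal within 60° of vertical) inside an ROI box.
* `build_sigmoid_surface()` casts 256 Fibonacci-sphere rays from centreline
  samples every 0.5 mm and reconstructs the bounding surface of the hit
  cloud by morphological closing with a ball of radius 1/α (α = 0.1 → 10 mm),
  isosurfaced by marching tetrahedra. For tube-like clouds this closing
  coincides with an alpha-shape hull at the tolerances used downstream
  (straight-channel volume within a few percent of the analytic capsule);
  we read the published α = 0.1 as the inverse ball radius, the convention
  of the common alpha-shape libraries. The sigmoid surface is subtracted
  from the skull base by containment-based face removal
  (`subtract_enclosed_faces()`), which suffices because only distances to
  the remaining faces are consumed.
* `build_entry_region()` samples the retroauricular planar domain — a
  30 × 30 mm sagittal square, anterior edge at the ear-canal centre,
  vertically centred on it, plus a 10 × 10 mm anterosuperior extension
  towards the zygomatic process — with a deterministic row lattice of
  exactly `n_points` (default 5000) near-evenly spaced samples, projected
  laterally (−x) onto the outer surface. A deterministic lattice rather
  than jittered sampling keeps left/right twins and reruns bit-identical.

## Canal centrelines and targets

`extract_centreline()` voxelizes the canal lumen at 0.1 mm, then finds the
medial path: interior voxels are graded by their distance to the wall,
endpoints are the geodesically farthest voxel pair (snapped to the deepest
voxel nearby, since the raw farthest pair sits on the end-cap rim), and the
path is the Dijkstra geodesic through the 26-connected voxel graph with edge
weights `len/(depth + 0.05)²`, which hugs the deep axis. The path is
Gaussian-smoothed (σ = 0.25 mm), extended to the end caps by
curvature-following quadratic extrapolation, and resampled at ≤ 0.2 mm with
symmetric-difference tangents over a ±0.5 mm window (unbiased on circular
arcs, robust to sub-voxel wiggle). On a torus-arc phantom the result stays
within 0.1 mm of the analytic circle and within 1% of the analytic arc
length; a thinning-based skeleton would serve equally, but no 3-D thinning
implementation exists in this package's dependency set and the medial
geodesic achieves the same contract with fewer moving parts.

`locate_targets()` places the **electrode target** at the centreline point
closest to the nerve target, identifies the **ampullary end** as the
centreline end nearer the nerve target, and puts the **fenestration site**
2 mm (default) along the centreline away from the ampulla, with the tangent
oriented from fenestration towards the electrode target.

## Clearance and the exposed-lumen model

Distance fields (`build_distance_field()`) sample the *exact*
point-to-surface distance on a regular grid (default 0.125 mm), signed
negative inside closed structures via angle-weighted pseudonormals; the open
skull-base sheet uses unsigned distances. Off-node queries interpolate
trilinearly and refuse to extrapolate. Trajectory clearance samples the path
at the same resolution (both endpoints included), subtracts the local drill
radius — piecewise constant 0.5 mm at the tip, 0.6 mm from 4 mm and 1.25 mm
from 14 mm behind the tip, the step applied *at* the threshold (conservative)
— and reports per-obstacle minima and their minimum, the safety margin.
Collisions yield negative margins and are never clipped. The target canal is
excluded from its own trajectory's obstacle set, since the drill must enter
it.

The idealized fenestration model (`exposed_area()`) treats the canal as a
straight cylindrical lumen and the drill as a cylinder with hemispherical
tip whose centre stops on the canal axis; the swept volume is then exactly
the set of points within the tip radius of the backward drill half-line, so
wall containment is analytic and the area integral is computed by refined
quadrature (doubling until < 1% change). The area grows steeply as the entry
angle becomes tangential, which motivates the 30° ideal angle used by the
optimizer.

## Accessibility and mutual optimization

An entry point is *accessible* for a canal when margin > threshold
(strictly) and entry angle < 80° (strictly); accessibility of a case/canal
is the percentage of accessible entry points. `optimize_mutual()` searches
accessible triples (one entry per canal) with every pairwise 3-D entry
distance < 12.5 mm and minimizes `Σ(αᵢ − 30°)²`. The search is exhaustive
with branch-and-bound pruning (canals ordered by candidate count, candidates
by objective), so it returns the exact discrete optimum; ties break by
smaller maximum pairwise distance, then lexicographic entry index —
deterministic output. Feasibility additionally verifies the minimal
enclosing circle of the three entries (in the entry-region chart) against
the 15 mm mastoidectomy: the pairwise bound already implies a diameter of at
most 2·12.5/√3 ≈ 14.43 mm in the worst (equilateral) case, which is how the
12.5 mm pairwise constraint and the 15 mm circle are mutually consistent.
Pairwise distances are measured in 3-D; the circle in the planar chart —
chart distances are bounded by 3-D distances, so the guarantee carries over.

## Numerical choices and degenerate inputs

* Voxelization/field spacing: 0.1 mm and 0.125 mm defaults; interpolation
  error is bounded by twice the spacing in the tests.
* Empty crops, missing superior faces, fenestration offsets beyond the arc,
  out-of-bounds field queries, non-watertight lumina (no interior voxels),
  and fragmented lumen components (< 50% in one connected component) all
  raise early, named errors rather than propagating garbage.
* Entry-region projection failing for more than 1% of samples is an error
  (the domain must be covered by the outer surface).

## Problem sizes used by the tests and the acceptance script

The shipped tests and `scripts/acceptance.R` exercise the identical code
paths at reduced problem sizes, a deliberate package choice so the whole
suite runs comfortably on one core: 200 entry points (5000 default),
0.5 mm field spacing and path sampling (0.125 mm default), 2 mm² outer
face area (0.1 mm² default), 96 sigmoid rays per sample (256 default), and
a 10-case cohort. The canal voxel pitch stays at the 0.1 mm default. All
accuracy-sensitive checks (distance-field error, centreline recovery,
exposure model, optimizer exactness) run at the full default resolutions on
phantoms.

## Known limitations

* The synthetic cohort's variation ranges are plausible but not calibrated
  to population morphometry; absolute accessibility percentages of the
  synthetic anatomy are not comparable to clinical cohorts.
* Boolean subtraction is containment-based (faces removed, not re-meshed);
  adequate here because only distances to surfaces are consumed.
* Robot kinematics, drill deflection and the common crus of the superior
  and posterior canals are out of scope; canals are treated as independent
  simple arcs, matching per-canal segmentations.
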