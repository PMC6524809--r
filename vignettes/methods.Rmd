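---
title: "Quantifying segmentation-induced variability in aneurysm morphometry and hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying segmentation-induced variability in aneurysm morphometry and hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aneumorph)
```

## The problem

When several observers (or algorithms) segment the same cerebral
angiography volume, every group obtains a slightly different lumen
surface. Those differences propagate into every quantity derived from
the surface: vessel radii, the aneurysm neck and sac shape, and — once
blood-flow simulations are run on the segmentations — wall shear stress
and intra-aneurysmal flow. `aneumorph` implements the measurement side
of that chain as a reusable pipeline: given an ensemble of triangulated
vascular surfaces of one vasculature (and, optionally, time-resolved
flow fields on them), it computes a standard set of morphological and
hemodynamic parameters per surface and summarises their spread across
the ensemble.

A companion synthetic module generates vascular phantoms with fully
known geometry and analytic flow, so that every stage of the pipeline
can be verified against closed forms and so that the whole ensemble
analysis can be exercised end to end without any external data.

## The measured quantities

For each segmentation the pipeline computes:

* **Centerline profiles.** A lumen centerline between two seed
  landmarks, carrying the *maximum inscribed sphere radius* at each
  point (the local vessel calibre) and, when a velocity field is
  available, the cycle-averaged velocity magnitude. Profiles from all
  groups are resampled on a common arc-length grid anchored at the
  shared inlet landmark, and the per-station sample standard deviation
  forms a variability band; its station-average is the scalar
  radius-variability measure.
* **Morphology.** The *ostium* (neck plane) is defined as the smallest
  planar lumen section that separates the aneurysm sac from the parent
  vessel. From it follow the ostium area, the parent-vessel
  cross-sectional area at a station proximal to the ostium, the sac
  volume `V` and lateral surface `S` (cut and capped at the neck), and
  the non-sphericity index

  `NSI = 1 - (18 pi)^(1/3) V^(2/3) / S`,

  a dimensionless shape measure that equals `1 - 2^(-1/3)` (about
  0.206) for a perfect sphere when `S` is the full bounding surface and
  grows as the sac elongates. Whether the neck cap belongs in `S` is a
  convention; the package reports both `nsi` (cap excluded, the
  primary value) and `nsi_with_cap`.
* **Hemodynamics.** From a time-resolved velocity field: the
  cycle-averaged *neck inflow rate* (positive part of the ostium flux),
  the parent-vessel flow rate (signed section flux), and the
  volume-weighted spatial mean velocity in the sac. From a wall shear
  stress field: the time-averaged WSS magnitude per wall sample,
  `AWSS = (1/T) \int |WSS| dt`, its area-weighted sac mean, and the
  oscillatory shear index
  `OSI = (1/2) (1 - |\int WSS dt| / \int |WSS| dt)`, which is 0 for
  unidirectional and 0.5 for fully reversing shear. The
  vector-versus-magnitude order is strict: the magnitude sits inside
  the integral for AWSS and outside the numerator integral for OSI.
  Iso-velocity volume fractions (threshold 0.3 m/s by default) support
  qualitative flow comparisons.
* **Ensemble statistics.** Per aneurysm and parameter: group count,
  median, sample (n−1) standard deviation and relative standard
  deviation; per parameter a `mean` row averaging the per-aneurysm
  values unweighted; five-number box-plot statistics with 1.5 IQR
  fences (outliers are reported, never excluded).

Flow modelling constants follow the common cerebral-CFD protocol
(incompressible Newtonian blood, density 1055 kg/m³, viscosity
0.004 Pa·s, 1 ms solver step, three cycles with the last analysed) and
are recorded in `simulation_config()`. Geometry is always in
millimetres and field values in SI; flow rates are reported in ml/s,
which conveniently equals mm² × m/s.

## Algorithms and the choices behind them

**Centerline extraction** voxelises the lumen interior (ray-parity on a
cell-centred grid), computes an exact Euclidean distance transform with
a bounded separable scan, and finds the least-cost path between the
seeds with per-step cost `1/d²`, which pins the path to the medial
axis. The path is smoothed, resampled, and each node is projected to
the local medial position by maximising the wall distance in the plane
orthogonal to the local tangent (pattern search; the search uses the
surface vertex cloud, which for meshes whose vertices lie on the true
surface overestimates the exact distance by under a percent at the
resolutions used, and the final radius is the exact point-to-triangle
distance). The medial projection only moves on strict improvement, so
nodes in cap-limited plateau regions — near flat vessel terminations,
where the medial set is a disk rather than a curve — stay put instead
of drifting with the search stencil. Radius profiles on analytic tubes
are recovered to well under 2% relative error for grid resolutions at
or below an eighth of the vessel radius; seed landmarks should sit at
least one local radius away from flat terminations, where the
inscribed sphere is genuinely cap-limited.

A distance-field least-cost path was chosen over a Voronoi-based medial
axis because it is self-contained, deterministic and directly
verifiable against analytic tube geometry; the deliverable (centerline
plus inscribed-sphere radius) does not depend on the extraction
algorithm.

**Ostium detection** operationalises "smallest separating plane" as a
search: candidate origins sample the segment from a dome seed (a point
inside the sac) to its nearest parent-centerline point; candidate
normals sample a 10°-resolution hemisphere oriented toward the sac,
followed by Nelder–Mead refinement of the origin offset and two tilt
components. A candidate is feasible when the dome seed lies on its sac
side, both centerline ends and the entire parent centerline lie on the
vessel side, and the planar lumen section contains a loop enclosing the
dome-seed projection but neither end projection. The minimal-area
feasible candidate is then verified exactly: the surface is cut at the
plane (exact edge splits, no voxelisation), and the sac-side component
containing the dome seed must carry exactly one boundary loop, keep
clear of the vessel lumen at the ends, and leave only sliver fragments
(under 1% of the sac area) elsewhere — slivers occur when the minimal
plane grazes wall-noise bumps and are discarded rather than treated as
sac material. When the unconstrained refinement step is rejected by
this verification (its optimum can sit below the lowest *clean* cut on
noisy walls), a constrained descent walks the accepted plane down its
own normal as long as the smaller section still passes — without it, a
noisy neck can be over-cut by a factor of two. Cuts are exact on
triangles because the section areas enter the summary tables at
three-figure precision.

**Flux quadrature** fan-triangulates the section polygon about its
centroid, splits each fan triangle into congruent subtriangles
(centroid rule), and interpolates the velocity field at the quadrature
nodes by inverse-distance weighting (power 2) of the four nearest
volumetric samples — a mesh-agnostic choice that works identically for
solver cell-centre exports and synthetic point clouds. Refining the
subdivision monotonically reduces the flux error on Poiseuille fields;
the defaults recover analytic fluxes within 2% at the shipped sampling
densities. Very dense section polygons are decimated to at most 72
vertices before fan triangulation; the induced area perturbation is
far below the quadrature tolerance.

**Neck inflow** averages the positive part of the ostium flux over the
cycle. An alternative convention halves the total exchanged flux; the
positive-part definition was chosen because it is the direct reading of
"flow entering the sac" and satisfies the inequality
`inflow >= signed flux` with equality exactly when no outflow occurs.

**Relative standard deviation** is std/mean × 100 (the secondary
std/median value is also emitted, since published tables rarely state
the denominator). Zero-shear wall samples get OSI 0 by convention (the
defining ratio is 0/0 there); their count is attached to the result.

## The synthetic generator

Phantoms are constructive solids — a straight or arc-shaped tube
(constant or linearly tapering radius), an optional spherical sac
joined through a cylindrical neck stalk of prescribed radius, and
optional cylindrical side branches — surfaced by marching tetrahedra on
a uniform grid of the signed implicit field. Marching tetrahedra is
watertight by construction and the six-tetrahedra cube split keeps
faces conforming. The neck-stalk construction makes the ostium ground
truth exact and robust: every plane across the exposed stalk is a
separating section of area `pi a²`, so the detected minimal plane sits
on a plateau rather than at a knife-edge, and the sac volume and
lateral surface follow spherical-cap closed forms.

Segmentation variability is emulated by offsetting vertices along the
surface normal with a smooth random field: a fixed basis of Gaussian
bumps (80 centres, 8 mm length scale by default) with per-group
standard normal coefficients, row-normalised so the pointwise
across-group standard deviation equals the prescribed noise level
(0.13 mm by default) at every vertex. Smooth correlated noise is
essential — real segmentation differences are coherent over- and
under-estimations of the wall; independent vertex jitter would destroy
mesh quality without resembling any plausible segmentation. Optional
per-group neck dilation/erosion (uniform in ±`neck_bias` around the
neck) and side-branch dropout (the group is rebuilt from the
branch-free solid, so the stump is capped smoothly) reproduce the two
canonical segmentation disagreements. A fold-over guard damps the
amplitude only when a contiguous fraction of full-sized triangles
reverses orientation; isolated skinny iso-surfacing triangles reorient
under any offset and are ignored by the guard.

Flow fields are quasi-steady Poiseuille at every instant: axial
velocity `2 Q(t) (1 - rho²/r²) / (pi r²)` and wall shear
`4 mu Q(t) / (pi r³)`, with a fixed flow fraction leaving through each
side branch. Quasi-steady profiles were preferred over Womersley
because every metric then has an exact closed form at every instant,
which is what makes the generator an oracle; pulsatile inertia is
deliberately out of scope. The sac interior carries a solid-rotation
field whose rate is calibrated on the generator's own samples so the
sac-mean speed at cycle-mean flow equals the prescribed value; the sac
wall carries a prescribed shear magnitude. Both are modulated by
`Q(t)/Q_mean` with the true (trapezoidal) cycle mean in the
denominator, so cycle averages are exact. The inflow surrogate is a
two-harmonic curve with exact mean; measured waveforms can be supplied
as CSV and are scaled to each group's inlet area by the square law
`Q ∝ D²` with `D = 2 sqrt(A/pi)` — under which the plug inlet velocity
`Q/A` is independent of the segmentation's inlet calibre, the property
that makes inlet conditions comparable across groups.

## The synthetic five-aneurysm study

`run_pipeline(run_config())` reproduces the structure of a
multi-aneurysm segmentation challenge: five phantoms whose sac
diameters (5.6, 1.5, 4.4, 4.6, 4.9 mm) span a clinical multi-aneurysm
case, parent radii of 1.1–1.3 mm and cycle-mean inflows of
1.6–3.3 ml/s in the cerebral range, each segmented by 24 groups with
0.13 mm wall noise and ±0.15 mm neck bias. Per group the pipeline runs
centerline extraction (grid at a sixth of the parent radius, profile
spacing twice that), ostium detection, sac isolation, inlet-area
square-law waveform scaling, analytic flow on the group's own axis and
radius profile (13 time samples per cycle, 0.35 mm field spacing), and
all eight parameters. Failures are isolated per group and flagged in
the table. On one CPU the full 5 × 24 study completes in roughly ten
minutes; these problem sizes were chosen so the whole analysis stays
desk-scale while each stage remains within its verified tolerance.

What the synthetic study does *not* emulate: patient-realistic
anatomy (no bifurcating trees beyond single side branches, no Circle of
Willis), Navier–Stokes hemodynamics (so secondary flows, inflow jets
and oscillatory shear patterns are absent — OSI is structurally near
zero in the synthetic fields), wall compliance, and non-Newtonian
rheology. Passing the synthetic acceptance experiments therefore
validates the measurement operators and the ensemble statistics, not
the physics of any particular simulated flow; CFD-derived variability
figures require user-supplied solver exports, for which the package
exposes every post-processing step (`read_field_series()` →
`awss()`/`osi()`/`plane_flux()`/`sac_means()`).

## Numerical details and degenerate inputs

* Vertex merge tolerance is 1e-6 mm — five orders below angiographic
  voxel size, so only numerically duplicated vertices (e.g. per-facet
  STL records) merge.
* Outward orientation is enforced by requiring positive signed volume;
  wall-vector conventions and flux signs depend on it.
* Self-intersection checking tests all bounding-box-overlapping
  triangle pairs exactly below 1e5 triangles and subsamples above.
  Exactly coincident contact (shared edges, mirror-symmetric
  crossings) is treated as touching, not intersecting.
* The bounded-window distance transform doubles its scan window until
  it covers the largest interior distance, so it is exact.
* Planar cuts nudge exact on-plane vertices by 1e-12 mm so every
  triangle classifies cleanly; section loops on non-manifold patches
  drop unpaired segments rather than failing.
* A single-sample field series is a valid steady field: cycle averages
  return the sample itself.
* Degenerate requests raise classed errors (`aneumorph_seed_error`,
  `aneumorph_isolation_error`, `aneumorph_coverage_error`, ...) so
  ensemble drivers can triage failure reasons; a sac melted into the
  vessel is an isolation error, mirroring the corresponding
  segmentation artifact.

## Acceptance experiments

Two ensemble-scale experiments connect the generator to the analysis
and are rerun by `scripts/acceptance.R`:

* **Band recovery.** 24 segmentations of a 48 mm straight vessel with
  0.13 mm injected wall noise; the centerline radius band must recover
  0.13 mm within 15%. The vessel is long relative to the 8 mm noise
  correlation length so the band average carries enough independent
  stations for that tolerance to be a sampling-error bound rather than
  luck.
* **Branch-dropout divergence.** Six groups of a branched vessel, half
  missing the side branch, equal inlet fluxes: downstream of the
  divergence point the velocity band grows by an order of magnitude
  while the radius band stays flat — the geometric signature that
  radius agreement does not imply flow agreement.

## Known limitations

* The ostium search assumes a single sac reachable from the dome seed;
  multi-lobed aneurysms and daughter sacs are not decomposed.
* Landmarks (seeds, dome points) come from configuration; there is no
  automatic detection across datasets.
* The centerline is a single source-to-target path; bifurcation trees
  require multiple calls.
* Inverse-distance interpolation smooths sharp near-wall gradients;
  flux and mean-velocity accuracy is tied to the field sampling
  density (the shipped densities keep it within the stated 1–2%).
* Surfaces are read from STL (ASCII and binary), PLY (ASCII) and OBJ;
  binary PLY and solver-specific unstructured-grid XML are not parsed —
  export to the columnar CSV field format instead.
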