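# aneumorph

Morphometric and hemodynamic variability analysis for segmented
vascular surfaces.

When several research groups segment the same cerebral angiography
volume, each obtains a slightly different lumen surface, and every
quantity derived from the surface inherits that spread — vessel radii,
aneurysm neck and sac shape, and (once flow is simulated on the
segmentations) wall shear stress and intra-aneurysmal flow.
`aneumorph` implements the measurement pipeline for quantifying that
segmentation-induced variability:

* **Geometry I/O** — STL (ASCII/binary), PLY and OBJ readers with
  cleaning and validation (watertightness, orientation,
  self-intersection); exact surface area and divergence-theorem volume.
* **Centerlines** — lumen centerlines by a distance-transform
  least-cost path with medial projection, carrying the maximum
  inscribed sphere radius; per-ensemble profile alignment and
  variability bands.
* **Sac morphometry** — ostium detection as the smallest separating
  planar section, exact cut-and-cap sac isolation, ostium area,
  parent-vessel cross-section, sac volume and the non-sphericity index
  `NSI = 1 − (18π)^(1/3) V^(2/3)/S`.
* **Flow metrics** — time-averaged wall shear stress
  `AWSS = (1/T)∫|WSS|dt`, oscillatory shear index
  `OSI = ½(1 − |∫WSS dt| / ∫|WSS|dt)`, planar flux integrals, neck
  inflow rate, sac spatial means and iso-velocity fractions, computed
  from time-resolved field exports.
* **Boundary conditions** — pulsatile inflow waveforms with square-law
  scaling (`Q ∝ D²`) to each segmentation's inlet area and
  plug-velocity conversion.
* **Ensemble statistics** — median / sample std / relative std tables
  per aneurysm and parameter, box-plot statistics with Tukey fences,
  CSV/JSON reports.
* **Synthetic phantoms** — watertight vessel-plus-sac solids with
  closed-form ground truth, smooth correlated segmentation-noise
  ensembles, and quasi-steady Poiseuille flow fields that make every
  metric analytically checkable.

## Worked example

Generate a sphere-on-vessel phantom, perturb it like a disagreeing
segmentation ensemble, and measure one group:

```r
library(aneumorph)

ph <- make_phantom(phantom_spec(
  length = 24, radius = 2,
  sac = list(neck_radius = 1.2, sac_radius = 3, station = 12)))

cl  <- extract_centerline(ph$surface, c(3, 0, 0), c(21, 0, 0), voxel = 0.3)
mo  <- morphometrics(ph$surface, ph$truth$sac_center, cl)
print(mo)
#> morpho_record: ostium 4.71 mm^2, parent 12.54 mm^2, V 113.76 mm^3, NSI 0.186
c(truth_ostium = ph$truth$ostium_area, truth_volume = ph$truth$sac_volume)
#> truth_ostium truth_volume
#>     4.523893   112.522595
```

The detected ostium area (4.71 mm²) and sac volume (113.8 mm³) sit
within a few percent of the constructed ground truth (π·1.2² =
4.52 mm² and the spherical-cap volume 112.5 mm³). The full ensemble study —
five phantom aneurysms, 24 perturbed segmentations each, morphology
plus synthetic hemodynamics, summarised like a challenge variability
table — runs as:

```r
study <- run_pipeline(run_config(n_groups = 24, seed = 1))
print(study)
#> ia_study: 5 aneurysm(s) x 120 group rows (0 failures)
#>   mean relative std over aneurysms:
#>     ostium_area      ...
summary(study)       # the median / rel-std table
plot(study)          # box plots per parameter and aneurysm
```

With zero injected noise every relative standard deviation is exactly
0%; with the default 0.13 mm wall noise the morphological and
hemodynamic parameters spread by roughly 5–25% depending on the
aneurysm, which is the phenomenon the pipeline exists to quantify.

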