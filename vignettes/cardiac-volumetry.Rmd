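---
title: "Short-axis and rotational long-axis volumetry on digital heart phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-axis and rotational long-axis volumetry on digital heart phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiovol)
```

## The measurement problem

Left-ventricular (LV) volumes, ejection fraction and myocardial mass are the
workhorse quantities of cardiac MR. Two contouring strategies compete in
practice:

* **Short-axis (SAX) slice summation** ("Simpson's method"): a stack of planes
  perpendicular to the LV long axis; chamber volume is the sum of per-slice
  cross-sectional areas times the slice spacing. Its dominant error source is
  the *basal slice*: a slice near the mitral valve contains ventricular blood,
  atrial blood, or both, and its inclusion or exclusion moves the volume by a
  full slice's worth.
* **Rotational long-axis (LAX) volumetry**: N planes sharing the long axis at
  equal angular increments (six planes, 30°, in the clinical protocol). The
  mitral and aortic valve planes are seen in profile, so the base is
  unambiguous, at the price of sampling the azimuth at only 2N rays.

`cardiovol` implements both quantification arms on *contours* (ordered planar
polygons with slice geometry), together with a digital heart phantom whose
chamber volumes and wall mass are known in closed form. The phantom plays the
role that resin casts of explanted hearts play in ex-vivo validation work: a
ground truth against which both methods' systematic errors can be measured,
with a perturbation model standing in for human observers.

## The phantom

The LV endocardium and epicardium are concentric ellipsoids (semi-axes in mm,
long axis = +z, base up), truncated by the *mitral plane*, which crosses the
long axis at `lv_truncation_fraction * c` and may be tilted about +x by
`mitral_tilt` degrees. The left atrium (LA) is an ellipsoid resting on that
crossing, optionally carrying a Gaussian radial *appendage* bump

\[ r(\theta, z) = r_{\text{ellipse}}(\theta, z) +
   A \exp\!\left(-\tfrac{\Delta\theta^2}{2\sigma_\theta^2}
                 -\tfrac{(z - z_0)^2}{2\sigma_z^2}\right), \]

the simplest non-axisymmetric feature that can hide between rotational planes.

All truncated-ellipsoid volumes are closed-form, including the tilted case
(affine map to the unit sphere plus the spherical-cap formula); the appendage
contribution is evaluated by midpoint quadrature on a 2048 × 2048
(angle × level) grid, which agrees with the 0.1 mm voxel oracle to a few
parts in 10^5. An independent brute-force check, `voxel_volume()`, counts
voxel centres of a cubic lattice inside the surface.

Phase is modelled by radial contraction: at end-systole the endocardial
semi-axes (a, b) shrink by `es_scale`, so ESV/EDV = `es_scale`² and
EF = 100 (1 − `es_scale`²). The epicardium contracts by the radial factor
that conserves the truncated wall volume (solved per phantom by
`uniroot()`): myocardium is incompressible, so mass is phase-invariant by
construction and the conventional end-systolic mass measurement is unbiased
relative to end-diastole. The LA is phase-independent; LA volumes are
reported at ED.

### Preset study conditions

`make_phantom()` draws from uniform ranges chosen so the populations sit at
the two scales of interest:

| preset | LV EDV | LV mass (ED) | LA volume | EF |
|---|---|---|---|---|
| canine | 19–28 ml | 95–104 g | 8–16 ml | 54–64 % |
| human | 120–240 ml | 110–180 g | 50–90 ml | 44–64 % |

Elongation (c/a 1.9–2.4) and mild in-plane eccentricity (b/a 0.92–1.0) are
drawn per heart; the wall thickness is solved from the target mass at density
1.05 g/ml (the literature-standard myocardial density; ground-truth studies
weigh tissue and never state one). The basal truncation fraction defaults to
0.75, making the mitral annulus ≈ `sqrt(1 - 0.75^2)` ≈ 0.66 of the maximal LV
diameter — the anatomical ratio. (At 0.9 the neck is so narrow that an
oblique mitral plane never crosses an included slice and basal clipping would
have nothing to do.)

What the generator does **not** emulate: papillary muscles and trabeculations
(the two arms conventionally treat them differently; smooth walls sidestep
that ambiguity and its inter-method bias), the right ventricle, through-plane
motion, and image formation of any kind (inputs are contours, not pixels).
Passing tests therefore demonstrate the *geometric* error mechanisms of the
two methods, not their full clinical error budget.

## Short-axis quantification

`slice_sax()` places planes at spacing `thickness + gap`; each slice
represents the full effective spacing (the standard clinical attribution of
the gap to its slice, so 8 mm + 2 mm behaves as a 10 mm sampling of the same
plane positions). The stack is anchored with the basal-most ventricular plane
centre half a spacing below the mitral crossing — a technologist planning
full coverage — with `anchor_offset` exposed because real placements are
arbitrary within one spacing.

A slice is *included* in the LV iff its central plane lies apical to the
mitral plane at the long-axis crossing. `clip_basal()` then removes any
atrial sub-area of an oblique basal slice (polygon/half-plane clip along the
line where the mitral plane intersects the slice plane), formalising the
cross-referencing procedure clinical software implements visually. No
apical half-slice correction is applied: plain slice summation keeps the
thickness-bias experiment interpretable. The midpoint-rule structure makes
the volume error O(thickness²); averaged over anchor offsets the measured
log–log slope is 1.9–2.1, and the mean |bias| ordering across 10/8/5 mm
reproduces the thickness ordering seen in ex-vivo validation.

## Rotational long-axis quantification

`split_contour()` cuts each radial contour at the long axis into two radius
profiles (azimuths θ and θ+180°). Levels where a profile's boundary is
crossed more than once on a side — an appendage overhang — resolve to the
outermost crossing (conservative for cavity volume) and are flagged.

`rotational_volume()` integrates over a uniform grid of `n_levels = 256`
midpoint cells spanning the contours' axial extent (the basal truncation
edge bounds the grid, excluding mitral-valve blood). With 2N half-planes
sorted by azimuth, the raw triangle-fan cross-section is
\(\sum_k \tfrac12 r_k r_{k+1} \sin\Delta\theta_k\); the default
*chord correction* rescales each sector by
\(\Delta\theta_k / \sin\Delta\theta_k\), i.e. sector areas become
\(\tfrac12 r_k r_{k+1}\,\Delta\theta_k\). The correction factor is fixed by
requiring exactness on circles: an uncorrected 6-plane fan underestimates
every axisymmetric cross-section by 3/π ≈ 4.5 %, a formula artifact rather
than a sampling property. Corrected, solids of revolution are recovered
exactly at any N ≥ 2 and the result is invariant under rotation of the plane
set (spread < 0.01 %); doubling `n_levels` moves the default result by
< 0.1 %. Both variants are exposed.

The LA finding has a purely geometric mechanism here: an appendage narrower
than the 30° inter-plane angle and centred between planes is invisible to
all sampled azimuths, so the rotational volume falls strictly below the
voxel oracle while a 5 mm SAX stack resolves the bump. The magnitude is
phantom-dependent (≈ 4 % for the default test appendage); only the sign is
asserted. Conversely a narrow bump centred *on* a plane is over-weighted —
the rotational method's known behaviour for small structures. Convergence in
N is from below for star-shaped sections, but at very small N two plane sets
can miss a between-plane bump equally well, so monotonicity is only tested
across the coarse ladder N = 3, 12, 48.

## Observer emulation

`noise_model()` displaces each vertex radially about the contour centroid by
a smooth periodic Gaussian field (white noise circularly convolved with a
Gaussian kernel of SD `smoothness_scale` degrees, mean-removed, scaled to
`radial_sd` mm). Because vertices keep their angular order, the perturbed
polygon is star-shaped — hence simple — whenever all radii stay positive;
violations redraw with a fresh sub-seed up to 10 times. The zero-mean field
preserves enclosed area to first order (Monte-Carlo mean area within
σ²/r̄² ≈ 0.2 % of truth at 0.5 mm noise). Everything is deterministic per
seed, with per-contour sub-seeds derived by a fixed counter rule.

`basal_shift` carries the basal-slice decision: −1 drops the basal LV slice;
+1 appends the blood section of the next atrial-side plane (stored by
`slice_sax()`), i.e. atrial volume erroneously read as ventricular. Either
way the LVEDV changes by exactly that contour's area × spacing. In
`run_study()` the ideal readings are clipped (cross-referenced), while
observer readings are quantified *as traced*: the perturbed set represents
the reader's final decisions, and re-clipping would silently undo the basal
error the observer model exists to carry. With default observers (both arms
0.5 mm noise; second SAX reader shifts the basal slice) the SAX
inter-observer differences exceed the LAX ones for every LV measure — the
direction reported for clinical readers.

## Statistics

`bland_altman()` uses d = method − reference, sample SD (n−1), and fixed
± 1.96 SD limits of agreement ("95 % limits" by convention; an exact-t
multiplier is available but off by default). `paired_t()` and
`correlation()` delegate the non-degenerate arithmetic to `stats::t.test()`
and `stats::cor()`, with explicit handling of zero-variance differences
(t = 0, p = 1 for identical series; infinite t, p = 0 for constant non-zero
differences, both flagged). The coefficient of variation is defined as
100 · SD(d) / mean(reference); published CV columns for this comparison are
mutually inconsistent under every standard definition (including negative
values), so no attempt is made to match them. No multiple-testing
correction is applied. Signed percent bias is
100 (measured − truth)/truth, so negative means underestimation.

## Reproducibility and problem sizes

`run_study()` is a pure function of its `study_config()`: per-heart and
per-observer seeds are `master_seed + 1009·heart + 97·observer (+13 for the
LAX arm)`, so extending a study never reshuffles existing hearts, and two
runs write byte-identical CSV/JSON. The shipped test-and-acceptance workload
uses 12–20 phantoms per experiment (with 50 for the inter-observer
direction), 0.1–0.3 mm voxel oracles, 360-vertex contours (polygonal area
error < 0.01 % at 40 mm radius) and 256 integration levels; these sizes were
chosen so each experiment's discretization error sits well below the effect
it measures.

```{r}
ph <- make_phantom("canine", seed = 1)
ph
c(sax_5mm = stack_volume(slice_sax(ph, 5), chamber = "LV", layer = "endo"),
  lax_6pl = rotational_volume(slice_lax(ph, 6)),
  truth = analytic_volume(ph, "LV", "endo", "ED"))
```

## Limitations

* Smooth convex-ish chamber walls: highly irregular ventricles (aneurysm,
  heavy trabeculation) violate both the star-shape assumption of the
  rotational integrator and the first-order area preservation of the noise
  model.
* The observer model has no systematic reader bias (zero-mean fields); only
  variability and basal misassignment are emulated, so absolute
  inter-observer magnitudes are not comparable to human readers — only
  orderings are.
* No image formation: partial-volume averaging *within* a slice is collapsed
  into the central-plane section; the thickness bias measured here is the
  sampling component only.
* Reading-time comparisons are outside scope entirely (human/hardware
  bound).
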