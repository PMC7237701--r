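---
title: "Methods: independent second-check dose calculation for HDR brachytherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: independent second-check dose calculation for HDR brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrcheck)
```

## Why a volumetric second check

High-dose-rate (HDR) image-guided adaptive brachytherapy delivers large
doses per fraction from a stepping Ir-192 source, and every re-optimized
plan should be recomputed independently of the treatment planning system
(TPS) before delivery. Classical second checks recompute a handful of
point doses; `hdrcheck` recomputes the full 3D dose distribution, so the
check extends to dose-volume histogram (DVH) parameters (D90%, D2cc, ...),
radiobiological (EQD2) totals, and gamma comparisons of whole dose planes.

## The dose model

The engine evaluates the AAPM TG-43U1 line-source formalism in water:

$$\dot D(r,\theta) \;=\; S_K \,\Lambda\,
\frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\, g_L(r)\, F(r,\theta),$$

with $r$ the distance (cm) from the active source center, $\theta$ the
polar angle from the source long axis, $r_0 = 1$ cm, $\theta_0 = 90°$.
$S_K$ is the air-kerma strength (U), $\Lambda$ the dose-rate constant
(cGy h⁻¹ U⁻¹), $g_L$ the radial dose function and $F$ the 2D anisotropy
function, both normalized to 1 at the reference geometry. The geometry
factor is $G_L = \beta/(L\,r\sin\theta)$ with $\beta$ the angle subtended
by the active length $L$ at the point; on the source axis the closed form
$(r^2 - L^2/4)^{-1}$ applies. Dose to a point is the dwell-time-weighted
superposition $\sum_i \dot D_i\, t_i/3600$ (cGy).

Numerical choices:

* **Interpolation.** $g_L$ is interpolated linearly in $r$; $F$
  bilinearly in $(r, \theta)$. TG-43 tables are dense enough that
  higher-order schemes buy nothing and risk overshoot near the source.
* **Extrapolation.** Queries outside the table range clamp to the table
  edge and emit one warning per call; TG-43 tables simply do not define
  values there, so predictable behavior beats silent extrapolation.
* **On-axis branch.** The $\beta$ form degenerates (0/0) as
  $\sin\theta \to 0$; below $\sin\theta < 10^{-6}$ the engine switches to
  the on-axis closed form. At table resolution no discontinuity is
  visible.
* **Units.** Geometry is carried in mm (DICOM convention) and converted
  to cm only inside the kernel; doses are cGy, times seconds.
* **Near-source cap.** Grid voxels closer than $L/2$ to a dwell center
  receive that dwell's transverse-axis dose at $r = L/2$. The cap avoids
  singular voxel values inside the applicator lumen; the number of capped
  contributions is recorded in the volume metadata.
* **No decay correction.** $S_K$ is taken as stored in the plan; the
  check verifies the plan as planned, not as decayed to a delivery time.

The packaged `hdr_source_ir192()` tables are a *synthetic* stand-in with
values representative of published HDR Ir-192 (mHDR-v2 class) data. They
exercise the interpolating kernel realistically but are not consensus
data; clinical use requires reading a vendor table with
`read_source_model()`. The `toy_source()` ($g \equiv 1$, $F \equiv 1$)
makes the reference-geometry identity $\dot D = S_K \Lambda$ exact, which
anchors several tests.

## Source orientation in ring applicators

Dose anisotropy makes the source orientation matter. In a ring channel
the source travels a circle, and the older practice of orienting each
source along the chord to the next dwell position systematically lags
the true direction by half the angular step (22.5° for 8 dwells on a
full circle). The tangent method implemented here removes that bias:

1. **Ring plane.** Every non-degenerate triple of dwell positions
   proposes a plane normal (all $\binom{n}{3}$ triples for $n \le 12$,
   a deterministic stride subsample of at most 220 triples beyond). The
   winning normal minimizes the RMSE of point-to-plane distances; the
   circle (center, radius) is then fitted to the in-plane projections by
   linear least squares (Kåsa fit). Triples with triangle area below
   $10^{-6}$ mm² are rejected as collinear.
2. **Tangents.** Each dwell's direction is the circle tangent at its
   position, $\hat n \times (p - c)$ normalized, signed to advance along
   the channel's delivery order (positive dot product with the chord to
   the next dwell; to the previous one for the last dwell).

"Fit the circle in the RMSE-selected plane" is one of two readings of a
sphere/plane construction; both coincide for exact data, and for noisy
data the in-plane least-squares circle is the deterministic,
oracle-checkable choice made here. Tandem and generic channels keep the
chained-chord orientation (the last dwell reuses the previous
direction); nothing better is defined for them by the method, and a
straight tandem makes the chord exact anyway.

On the synthetic fixtures, noiseless rings are recovered exactly (to
1e-9 mm) and across 100 seeded rings with 0.05–0.2 mm position noise the
fitted normal and the tangent directions stay within 1° of ground truth
on average.

## Grids, structures and DVH metrics

Dose grids are rectilinear with selectable in-plane resolution — 2.5,
1.0 and 0.5 mm are the conventional choices, 1.0 mm the default — while
the slice spacing follows the structure set, because contours exist only
on imaging slices. Dose is evaluated at voxel centers with no volume
averaging, so refining the grid never changes values at shared centers
and grid-size effects on DVH parameters remain interpretable.

A voxel belongs to a structure iff its center lies inside the contour
polygon(s) of its slice, by the even-odd rule, with no partial-volume
weighting; a slice may carry several polygons (the applicator's annular
ring section), combined by even-odd parity. Each contour maps to the
nearest grid slice and is skipped (with a warning) if the mismatch
exceeds half the slice spacing. This transparent rule is exactly what
makes structure volumes depend on grid size, the mechanism the grid-size
comparisons probe: a 10 mm square holds 100 voxel centers per slice at
1.0 mm but 16 at 2.5 mm.

DVH metrics are computed from the exact sorted voxel doses — no
histogram binning, so bin width never enters; exported curves are binned
at 1 cGy for plotting only. $D_{x\%}$ is the minimum dose to the hottest
$x\%$ of the structure volume, $D_{x\mathrm{cc}}$ the minimum dose to the
hottest $x$ cm³; fractional voxel counts interpolate linearly between
adjacent sorted doses. The HR-CTV is evaluated both with and without the
applicator volume (mask AND NOT applicator) to expose the applicator's
effect on target coverage. Plan criteria follow the usual per-fraction
prescription (HR-CTV D90% at 550 cGy; bladder D2cc < 460 cGy; rectum and
sigmoid D2cc < 420 cGy, strict inequalities as written).

## EQD2 conversion

Doses are converted with the linear-quadratic model,
$\mathrm{BED} = n\,d\,[1 + d/(\alpha/\beta)]$ and
$\mathrm{EQD2} = \mathrm{BED}/[1 + 2/(\alpha/\beta)]$, with
$\alpha/\beta = 10$ Gy for tumor and 3 Gy for organs at risk by default
(overridable per structure). Kernel doses are cGy; the radiobiology layer
works in Gy and converts at the boundary. Course totals convert each
fraction at its own per-fraction dose and then sum — not one conversion
of the summed dose — matching how per-fraction DVH parameters are
tabulated clinically. Whole dose volumes can be converted voxelwise with
`eqd2_volume()`.

## Gamma comparison

Two distributions on the same grid are compared with the gamma index:
for each reference point, the minimum over nearby evaluated points of
$\sqrt{\Delta r^2/\mathrm{DTA}^2 + \Delta D^2/(\mathrm{tol}\cdot
D_\mathrm{norm})^2}$, with 3%/3-mm the default criteria, normalization to
the global maximum of the reference distribution, and $\gamma \le 1$
passing (the boundary passes; a 1e-9 tie tolerance absorbs float
round-off). The low-dose threshold defaults to 0 — every point is
evaluated — and is configurable because 10% thresholds are common
practice.

The search is exhaustive over evaluated grid points within 3×DTA,
followed by one level of 10× sub-grid refinement with multilinear
interpolation. The refinement descends into the *four* best coarse
candidates per point rather than only the best one: the best-candidate
choice depends on the criteria, and refining a single
criteria-dependent basin can leave the map non-monotone under criteria
tightening at isolated points. Four basins removed every such violation
in our toy-pair checks at negligible cost (the engine falls back to the
single best basin when the candidate table would exceed memory on large
volumes). In workflow runs the comparison is made on the plane through
the ring center containing the ring axis, extracted from both volumes by
trilinear resampling.

## The synthetic study conditions

All tests and the acceptance script run on a deterministic synthetic
fixture emulating a tandem-and-ring plan in a water-equivalent pelvis:

* ring: radius 15 mm, 8 dwells equally spaced on the full circle;
* tandem: 8 dwells over 40 mm along the ring axis, starting 5 mm above
  the ring plane;
* dwell times 20 s everywhere; $S_K = 40700$ U (a 10 Ci-class source);
  $\Lambda = 1.108$ cGy h⁻¹ U⁻¹, $L = 3.6$ mm;
* 5 fractions of 5.5 Gy prescribed;
* ellipsoidal HR-CTV (25 × 25 × 30 mm semi-axes) enclosing the ring,
  offset ellipsoids for bladder, rectum and sigmoid, and an applicator
  ROI built from a torus around the ring plus a cylinder along the
  tandem; contours at 1° vertex spacing on 2.5 mm slices;
* optional Gaussian dwell-position noise (σ up to 0.2 mm) for the
  geometry-recovery studies, with one seeded stream per fixture.

These values were chosen once as a realistic single condition for a
26/30-mm-class ring applicator. Two caveats define what passing tests do
and do not show. First, dwell times are uniform, not inverse-optimized,
so organ-at-risk criteria need not pass on the fixture — the criteria
check is exercised, including failures, which is precisely what a second
check must detect. Second, the phantom is water-equivalent convex
geometry with analytic contours; real anatomy brings heterogeneity
(outside the TG-43 model by design), non-convex contours and
inter-fraction variation, none of which these fixtures emulate. Agreement
on the fixtures validates the computational machinery, not clinical
accuracy for any particular patient.

Problem sizes used by the default test run and the acceptance script:
the full workflow runs at 1.0 mm in-plane resolution over the phantom
(≈ 3.4 × 10⁵ voxels, 16 dwells), the kernel oracle samples 200
geometries against a 10⁵-segment line integral, and geometry recovery
uses 100 seeded rings. These sizes make the whole suite run in a few
minutes on a single core while leaving every comparison at its stated
tolerance.

## Known limitations

* TG-43 water dosimetry only: no heterogeneity or shielded-applicator
  corrections (TG-186 model-based algorithms are out of scope).
* No transit dose between dwells and no source-decay correction.
* DICOM RT files are not read directly; plans, structures, doses and
  points travel in the package's documented text formats (the dialect
  arguments reserve the DICOM names and fail with a pointer to the text
  formats).
* Contours are not interpolated between slices; volumes inherit the
  stack-of-polygons convention.
* Curved tandems would need spline orientation; only straight-chord
  orientation is provided for non-ring channels.
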