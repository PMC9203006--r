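---
title: "Methods: moving-boundary Stokes analysis of trabecular hemodynamics"
author: "trabflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moving-boundary Stokes analysis of trabecular hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

The early embryonic zebrafish ventricle is a chamber some 30--50 um across
whose inner wall is corrugated by trabeculae: muscular ridges covered by
endocardium that protrude into the lumen, separated by intra-trabecular
grooves. At this scale blood behaves as a creeping flow. With plasma
viscosity 1.5 cP, blood 7.35 cP, density 1.025 kg/L, wall speeds of a few
hundred um/s and a cardiac period of about 0.25 s, the Reynolds number is
well below one and the Womersley number around 0.1 (both are recomputed and
reported for every solve in the `audit` table of `solve_cycle()`). Inertia
and transient acceleration are therefore negligible: at every instant the
flow is the unique Stokes flow compatible with the instantaneous wall
velocity. `trabflow` exploits exactly this structure.

The package asks three questions about that flow system:

1. How does wall shear stress (WSS) distribute over ridges and grooves, and
   how does it depend on the assumed viscosity?
2. What component of the wall motion -- rigid translation of the chamber or
   deformational squeezing of the grooves -- actually generates
   intra-trabecular WSS?
3. What does the corrugated geometry do for the tissue: how much endocardial
   area strain is needed to pump a given stroke volume, compared with a
   smooth chamber moved by the same volume waveform?

## Model and numerical procedure

### Quasi-steady Stokes instead of transient Navier--Stokes

The single largest modelling decision is to replace a transient
dynamic-mesh Navier--Stokes simulation by a sequence of independent steady
Stokes solves, one per cardiac frame, each driven by the finite-difference
wall velocity of that frame. At Re << 1 and Wo << 1 the neglected terms are
of relative order Re and Wo^2. A corollary is that the velocity field of a
wall-driven solve is independent of viscosity, so WSS is exactly
proportional to the viscosity used to convert shear rate to stress -- the
viscosity-scaling law holds to solver precision rather than approximately.
The `quasi_steady_valid` flag in every audit row records whether the
assumption is self-consistent for that run.

### Discretization

Each frame's fluid domain (the region enclosed by the endocardial boundary,
minus trapped cells) is triangulated from scratch: the boundary nodes are
kept verbatim (node identity is the persistent object through the cycle;
the volume mesh is disposable), the interior is filled with a jittered
hexagonal lattice at the target edge length and Delaunay-triangulated
(`interp`), the triangulation is clipped to the domain, every boundary
segment is verified to be present (interior points blocking a segment are
removed and the mesh rebuilt), and interior vertices are relaxed by three
Laplacian passes. Where opposite walls or a cell and the wall approach
within about three edge lengths, the lattice is refined locally so the gap
retains interior resolution. Remeshing per frame was chosen over mesh
deformation because groove closure produces large boundary excursions that
would destroy a deformed mesh's quality.

The Stokes system uses inf-sup-stable Taylor--Hood elements (quadratic
velocity, linear pressure) in the gradient (vector-Laplacian) form, whose
natural boundary condition `mu du/dn - p n = -p_ref n` is the discrete
"zero-reference-pressure" opening: it reproduces Poiseuille flow exactly on
a rectangular channel, which the test suite exploits as a machine-precision
oracle. Walls are moving no-slip Dirichlet boundaries. The saddle-point
system is solved through the pressure Schur complement: one sparse Cholesky
factorization of the scalar velocity block (CHOLMOD) serves both velocity
components, and conjugate gradients preconditioned with the lumped pressure
mass matrix solve for pressure to a relative tolerance of 1e-12, falling
back to a direct sparse LU if CG stalls. Problem sizes are around 1.5--3 k
pressure and 15--30 k velocity unknowns for a ventricle frame at 1 um
resolution.

Wall shear rate is extracted as `t . (grad u + grad u^T) . n` at each wall
node from the P2 gradient of the adjacent boundary elements (averaged over
the two incident edges). Using the rate-of-deformation tensor makes the
value invariant under rigid wall motion, i.e. it is the shear rate in the
wall-relative frame; a rigidly translating sealed cavity yields exactly
zero. The sign convention follows the ring-traversal tangent, so a signed
per-node time series is well defined and direction reversals are visible to
the oscillatory shear index.

### Boundary phase schedule

The ventricular inlet is the open (zero-reference-pressure) segment while
the chamber fills and the outlet while it empties, switching at the extrema
of the enclosed-area waveform; the published description does not specify
the switching instants, so the extremum rule -- the least arbitrary choice
-- is used and the instantaneous sign of dA/dt decides each frame. Isolated
grooves keep their single cropping-plane opening open throughout. Sealed
(all-wall) problems check the compatibility of the prescribed wall flux and
gauge the pressure at one vertex.

### Mass audit

For every frame the solver reports
`|flux_open_rel + dA/dt| / max(|dA/dt|, eps)`, where `flux_open_rel` is the
fluid flux through the open segments measured relative to the moving
boundary and `dA/dt` is the area rate implied by the prescribed boundary
velocities. This residual is below 2% on all shipped fixtures and
experiments at default resolution and converges under refinement.

## The synthetic heart generator

No image data are available, so the study conditions are emulated by a
seeded parametric generator. Its defaults are the measured quantities:
inner diameter 40 um (valid range 30--50), intra-trabecular dimensions
drawn per groove from Gaussians 12.5 +/- 3.1 (longitudinal), 8.7 +/- 0.8
(radial), 21.7 +/- 10.7 um (circumferential) truncated at +/- 2 sd
(truncation avoids non-physical negatives; it narrows the realized spread
by roughly a tenth, which the sampling tests account for), cycle duration
0.25 s sampled at 25 frames (100 fps acquisition), trapped-cell diameters
in the 6--8 um range, and rigid rotation absent by construction (the
best-fit Kabsch rotation is measured and reported; it never approaches the
0.07 rad level below which rotations are neglected).

Choices the measurements do not pin down, fixed once and documented here:

* **Base chamber.** An eccentric oval `r(theta) = R0 (1 + e cos theta)`
  with eccentricity from the inner/outer curvature ratio (default 0.5);
  the bulged side is the outer curvature. Grooves are placed only on the
  outer-curvature arc (|theta| < 1.75 rad), with at least 2.5 um of ridge
  between adjacent grooves; an arrangement that cannot fit is rejected as
  infeasible packing. A 2D optical mid-section of a heavily trabeculated
  chamber cuts a small number of grooves; the default is `n_grooves = 2`.
* **Volume waveform.** Piecewise-cosine and C1-periodic with an
  early-systolic ejection, an early-diastolic filling wave, a diastasis
  plateau and a late-diastolic A-wave; ejection fraction defaults to 0.4
  of end-diastolic area, diastole to 0.6 of the cycle. At every frame the
  envelope scale is solved (1D root find, tolerance 1e-12) so the polygon
  area matches the waveform exactly.
* **Groove squeeze phase.** Groove dimensions were measured at end
  systole, when the thickened myocardium protrudes the ridges furthest;
  the generator therefore realizes nominal dimensions at end systole and
  shallows the pockets toward end diastole by the `squeeze_amplitude`
  fraction (default 0.5). The pocket area waveform is thus anti-phase with
  the chamber: grooves draw fluid in during systole and expel it in
  diastole, which is the squeeze-flow mechanism under study.
* **Translation.** An elliptical displacement loop with semi-axes (3, 1.5)
  um -- a realistic whole-heart excursion; the published record does not
  quantify it.
* **Trapped cells.** Circles riding the material deformation map of their
  host pocket plus a seeded two-harmonic wobble (default amplitude 0.25
  um), validated for clearance at every frame and returning to their start
  point after one period. Because a 6.5 um cell cannot survive a 50%
  squeeze of an 8.7 um pocket in a 2D section (in vivo the space escapes
  along the third dimension), cell experiments run with
  `squeeze_amplitude = 0.1` and draw host grooves conditional on feasibility,
  mirroring the fact that cells are observed in grooves that can hold them.
* **Smooth counterpart.** The trabeculated boundary is replaced by the
  analytic ridge-crest envelope (a morphological opening of the radial
  profile for externally supplied boundaries), rescaled at every frame so
  the enclosed area matches the trabeculated model frame by frame --
  "aggressive smoothing driven by the same motion field", with stroke
  volume matched by construction.
* **Motion decomposition.** "Translation" is the displacement of the
  outer-ring area centroid; deformation is the remainder. The published
  description does not state which rigid fit was removed; centroid
  translation is the assumption, and the two components recompose exactly.

What the generator does **not** emulate: the true 3D lobed anatomy (the
pipeline is a 2D section; 3D claims are tested as orderings, not absolute
values), endocardial folding and wall contact at deep squeeze, imaging
noise and segmentation error, and beat-to-beat variability. Passing tests
on synthetic geometry therefore validate the mechanisms and the solver, not
the absolute WSS magnitudes of any real embryo -- those depend on
unavailable image-derived geometries and are deliberately out of scope.

## Wall metrics

* `wss()`: tau = mu * gamma, per node and frame.
* `mixed_viscosity_wss()`: plasma viscosity on groove (and cell) surfaces,
  blood viscosity elsewhere -- cells larger than the groove mouth cannot
  enter, so intra-trabecular fluid is plasma. By linearity this equals
  node-wise selection from two single-viscosity conversions, which the
  tests assert as an identity.
* `tawss()`: time average of |tau| with periodic closure (uniform sampling
  makes the periodic trapezoid a plain mean).
* `osi()`: `0.5 (1 - |int tau dt| / int |tau| dt)`, the standard
  oscillatory shear index in [0, 0.5]; the original supplement defining the
  index is not available, so this standard form is adopted (its 0--0.5
  range matches the published color scales). OSI of identically zero shear
  is defined as 0. In 2D the signed tangential series captures direction
  reversal exactly.
* `classify_ridge_groove()`: automated surrogate for manual delineation --
  nodes deeper than a 1 um threshold beyond the smooth ridge-crest envelope
  are grooves; a manual mask overrides everything. On generated geometry
  the recovery of ground-truth groove nodes exceeds 90%.
* `area_strain()`: per-element relative area change between extruded
  end-diastolic and end-systolic surfaces in exact element correspondence.
  The summary is the area-weighted mean of |strain| with end-diastolic
  weights; the published work does not define its averaging, so this choice
  is recorded in the result object itself.
* `wilcoxon_exact()`: the exact signed-rank distribution by full
  enumeration of the 2^n sign assignments (computed via the rank-sum
  generating function; ties get average ranks, zeros are dropped with a
  warning). The test is one-sided by default: the minimum attainable
  p-value at n = 4 is 0.0625 one-sided and 0.125 two-sided, and only the
  one-sided value matches the printed significance floor; the sidedness is
  recorded in the returned object.

## Scenario experiments

`motion_decomposition_experiment()` runs replicate isolated grooves under
full motion, translation only, and squeeze only. "Drastically diminished"
is operationalized as below 25% of the full-motion WSS in every replicate
(in the Stokes limit a rigidly translating open pocket in fact produces
essentially zero wall-relative shear, because the traction-free opening
imposes no far-field resistance); "insignificant change" as a paired
one-sided exact Wilcoxon p above 0.05. Both thresholds are package choices
recorded here.

`cell_effect_experiment()` pairs identical grooves with and without a
trapped cell; `trabeculation_effect_experiment()` pairs trabeculated
ventricles with their smooth counterparts, comparing strain, stroke volume,
mixed-viscosity ridge/groove TAWSS and OSI. Endocardial averages exclude
opening nodes (whether the published averages included them is unstated;
the exclusion is recorded here). Replicate counts default to 6 grooves,
2 cell pairs and 4 ventricle pairs, matching the published sample sizes,
and every experiment is reproducible bit for bit from its seed list.

Problem sizes were chosen for interactive use on one CPU: mesh edge length
1 um for single-cycle viscosity runs, 1.2 um for the paired-ventricle
experiment, 0.7 um for isolated grooves and 0.45 um (with automatic
near-gap refinement) for cell runs; 25 frames per cycle throughout. At
these sizes the complete experiment suite runs in minutes while keeping the
mass-balance residual under 2% and mesh minimum angles above 20 degrees.

## Known limitations

* 2D section physics: out-of-plane leakage, lobed 3D geometry and
  three-dimensional groove connectivity are absent; orderings, not
  absolute magnitudes, are the claims.
* Blood is a continuum; a cell-resolved two-phase treatment (beyond the
  quasi-static trapped cells) is out of scope.
* Full wall contact and endocardial folding are not resolved; near-contact
  is handled by local refinement only down to the configured gap.
* The do-nothing opening is not Galilean invariant, so a translating open
  pocket sheds exactly zero shear rather than the small nonzero value a
  surrounding chamber would impose; the baseline (embedded-groove)
  scenario covers that regime instead.
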