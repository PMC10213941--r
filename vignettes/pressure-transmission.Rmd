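---
title: "Modelling CSF pressure transmission through the vestibular aqueduct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CSF pressure transmission through the vestibular aqueduct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqueduct)
```

## The physical picture

A cerebrospinal-fluid (CSF) pressure transient — a head impact raises CSF
pressure into the 0.5–300 kPa range — communicates with the inner-ear fluids
through the vestibular aqueduct (VA), a bony channel of average length
8.7 mm. The labyrinth is otherwise rigid and fluid-filled; its one compliant
relief boundary is the round window membrane (RWM). Transmitted pressure
therefore converts into RWM deflection and bending stress. In large
vestibular aqueduct syndrome (LVAS) the channel is congenitally widened
(Cincinnati criteria: midpoint width > 0.9 mm or operculum width > 1.9 mm),
and the question this package makes computable is: *how do the transmitted
pressure, the membrane deformation and its stress depend on the load level
and on the VA calibre, and how is the response timed relative to the load?*

The package models this with three coupled ingredients:

1. **A laminar duct.** The VA is reduced to a tapered circular channel whose
   hydraulic behaviour is captured by Poiseuille resistance
   $R = 8\mu L/\pi r^4$ and inertance $L_h = \rho L/\pi r^2$. Laminarity is
   established by the worked Reynolds number
   $\mathrm{Re} = \rho v d/\mu = 1000 \times 0.00547 \times 0.00086/10^{-3}
   \approx 5 \ll 2000$ (`reynolds_number()`).
2. **A closed incompressible cavity.** With no pressure outlet, every unit
   of volume that flows in through the VA must be stored by membrane
   bulging: $\dot V = q$ is the velocity-continuity condition at the
   fluid–solid interface in volume form. The cavity volume itself cancels
   and never enters the dynamics.
3. **A clamped elastic plate.** The RWM is a linear Kirchhoff plate, clamped
   along its rim, with volumetric compliance $C = \pi a^6/192 D$ (circle of
   radius $a$), $D = E h^3 / 12(1-\nu^2)$. The inner-ear pressure acting on
   it is $P_{ie} = V/C$ — traction continuity: the membrane feels only the
   cavity pressure, never the inlet pressure directly.

Together these give a linear two-state system,
$$ L_h \dot q + R_{tot}\, q + V/C = P_{in}(t), \qquad \dot V = q, $$
driven by a half-sine inlet pulse $P_{in}(t) = p_{max}\sin(\pi t/T)$ with
$T = 12$ ms (peak at 6 ms), observed for 25 ms.

## Parameters and defaults

| parameter | default | units | origin |
|---|---|---|---|
| VA length | 8.7 | mm | anatomical average |
| VA widths (operculum, midpoint) | grid: (1.2, 0.8) … (4.3, 3.3) | mm | measured reference geometries, models Normal and A–G |
| fluid viscosity $\mu$ | $10^{-3}$ | Pa s | water-like lymph |
| fluid density $\rho$ | 1000 | kg/m³ | water-like lymph |
| RWM area / perimeter | 2.031 / 5.131 | mm² / mm | measured means |
| RWM modulus $E$, Poisson $\nu$ | 3 MPa, 0.3 | — | elastic film values |
| RWM thickness $h$ | 60 | µm | see below |
| load peak $p_{max}$ | 10–300 | kPa | CSF transient range |
| pulse timing | peak 6 ms, duration 12 ms, window 25 ms | s | loading protocol |
| `alpha` | 1.0 | — | effective-lumen factor (below) |
| `zeta_add` | 1.0 | — | added damping ratio (below) |
| `dt` | $10^{-5}$ | s | integrator step |

**The membrane planform.** The measured area and perimeter are mutually
inconsistent with a circle (the equal-area circle's circumference is
5.052 mm, 1.6% below the measured 5.131 mm), so by default the planform is
the ellipse that reproduces both: `derive_membrane_ellipse()` solves
$\pi a_e b_e = A$ together with Ramanujan's perimeter approximation by a
bracketed root find in the aspect ratio (monotone in eccentricity,
tolerance $10^{-10}$), giving semi-axes 0.929 × 0.696 mm. A circle mode is
available (`membrane_spec(shape = "circle")`). The lumped compliance uses
the equal-area circle closed form; the `"fem"` simulation mode uses the
discrete solve on the true ellipse instead.

**The thickness.** A nanometre-scale RWM (60 nm) would make the plate about
$10^9$ times more compliant and produce kilometre-scale linear deflections —
mechanically absurd for a membrane of ~2 mm² span, and inconsistent with
reported RWM anatomy (tens of micrometres). The package default is therefore
**60 µm**; the configuration accepts any value but warns whenever a
sub-micrometre thickness is requested, so the choice is surfaced rather than
hidden.

**The effective lumen (`alpha`).** CT width measurements see the bony
channel; the conducting membranous duct inside it may be narrower. The
effective hydraulic radius is $\alpha \cdot w_{mid}/2$ with $\alpha = 1$ by
default (full bony lumen). `alpha` is the single honest geometric knob, is
recorded in every sweep's config snapshot, and is echoed in `report()`.

**The added damping (`zeta_add`).** The lumped reduction concentrates all
viscous loss into the duct's Poiseuille resistance. That leaves the
duct–membrane oscillator severely underdamped (damping ratio ~0.03 for the
normal geometry, ~$4\times10^{-4}$ for the widest), and an undamped
oscillator driven by a half-sine pulse *overshoots*: the transmitted
pressure would exceed the inlet peak by tens of percent and the overshoot
would be largest for the narrowest duct — inverting the physically expected
calibre ordering and contradicting the smooth, gently rising and falling
responses the three-dimensional simulations this model reduces show, where
post-pulse fluctuations are negligible. A distributed 3D cavity dissipates:
boundary-layer losses in the narrow duct, viscous shear in the cavity and in
the membrane itself are all absent from the two-state reduction. The package
therefore adds, by default, damping at the critical ratio
(`zeta_add = 1`, applied as an extra resistance
$2\zeta\sqrt{L_h/C}$): the response then tracks the pulse without resonant
ringing, transmitted pressure stays bounded by the inlet peak, and the
response lags the load by 0.5–2 ms, consistent with a peak arriving at
7–8 ms for a 6 ms load peak. `zeta_add` is configurable (including 0 to
study the undamped reduction) and is echoed in every report.

## The synthetic phantom

`build_phantom()` rasterizes a model into a labelled voxel volume emulating
a segmented temporal-bone CT: cochlea and vestibule as overlapping
ellipsoids, one semicircular-canal torus, and the VA as a tube along +x
whose diameter follows the piecewise-linear taper (inner opening = midpoint
width over the inner half, widening to the operculum width at the outer
end), with the external aperture flush with the volume boundary. The default
voxel spacing is 0.1 mm rather than the CT's 1 mm slice thickness: at 1 mm
the 0.8 mm normal aqueduct is sub-voxel and no width could be recovered; the
CT-like spacing remains available in the config for realism experiments (a
warning fires whenever spacing exceeds half the midpoint width).
Rasterization is pure geometry — deterministic and seed-free.

`measure_va_widths()` re-measures what the generator knows: it extracts the
VA centerline as ordered per-slice centroids from the inner opening to the
aperture, takes the cross-section perpendicular to the duct axis at the
arc-length midpoint and at the aperture, and returns each section's maximal
chord plus one voxel spacing (compensating the half-voxel erosion at both
ends of a chord between voxel centres). Two documented conventions resolve
ambiguities the source measurements leave open: "width" is the **maximal
chord** of the perpendicular cross-section (not a fixed axial-plane axis),
and the unmeasured **inner-opening width equals the midpoint width**. The
estimator is accurate to within one voxel spacing, which the tests assert
for spacings 0.05–0.2 mm; connectivity (single face-connected component
linking the vestibule to the boundary face) is verified via the voxel
adjacency graph, and defects are reported by name (missing, disconnected,
detached, not reaching the boundary).

What the phantom deliberately does **not** emulate: the cochlear spiral, the
"J"-curvature of the VA course (only arc length and cross-section enter the
hydraulics), partial-volume grey values, beam hardening or noise — so
passing width-recovery tests validates the morphometry pipeline on clean
geometry, not segmentation of real CT.

`extract_surface()` provides the 3D-modelling step: a box-filter smoothing
of the binary union (emulating surface smoothing of segmented models)
followed by marching-tetrahedra polygonisation, whose 6-tetrahedra cube
decomposition shares every face diagonal between neighbouring cubes, making
the surface watertight by construction; meshes export to binary STL and
legacy VTK.

## The membrane solver

`solve_plate()` solves the clamped-plate problem $D\nabla^4 w = p$ on the
ellipse by a Ritz–Galerkin method: the ellipse is mapped to the unit disk
($x = aX$, $y = bY$) and the trial space is
$w = (1 - X^2 - Y^2)^2\, P(X, Y)$ with $P$ a complete polynomial basis.
Every trial function is smooth and satisfies $w = \partial w/\partial n = 0$
on the ellipse exactly, so the clamped conditions and the curved boundary
carry no discretization error; the stiffness and load integrals are
polynomial and are integrated exactly (Gauss–Legendre radial × uniform
angular quadrature); the linear system is Jacobi-scaled and the basis degree
is capped at 10 to keep it well conditioned. The mesh
(`plate_mesh()`, polar rings × sectors with one centre node) sets the basis
degree through its characteristic element size and carries the nodes at
which deflection and surface stress are reported, the boundary ring, and the
triangles used for export and element-quality checks (degenerate triangles
are rejected by index).

Two properties of this discretization matter for interpretation:

* For **uniform pressure** the exact solution,
  $w = w_0 (1 - X^2 - Y^2)^2$, lies in the trial space at every degree, so
  maxima are exact up to arithmetic at all mesh sizes and the
  mesh-convergence study (`convergence_study()`, the element-size
  sensitivity test) plateaus immediately — relative changes are at machine
  epsilon rather than percents. The <2% plateau criterion is met by
  construction; the study is retained as the harness that would expose
  genuine convergence behaviour for non-polynomial (e.g. non-uniform-load)
  extensions.
* Stress recovery evaluates curvatures of the smooth solution directly at
  the nodes (no element averaging is needed); surface stress is
  $\sigma = 6M/h^2$ from the bending moments, and both the von Mises field
  and the principal bending stress are reported. At the clamped edge of a
  circle the stress state is $(\sigma_r, \nu\sigma_r)$ with
  $\sigma_r = 3pa^2/4h^2$, so the edge **von Mises** value is
  $\sqrt{1-\nu+\nu^2}\,\sigma_r \approx 0.889\,\sigma_r$ at $\nu = 0.3$ —
  the two quantities differ by 11% and the package keeps both explicitly
  (`max_stress` vs `max_bending_stress`) to avoid that ambiguity.

The solver is linear, so solutions scale exactly with pressure; the
transient driver exploits this by computing one unit-pressure membrane
response and scaling it along the $P_{ie}(t)$ series.

Deflections are **linear-theory** values. At 10 kPa the predicted maximum
already exceeds the 60 µm thickness ($w_{max} \approx 1.1$ mm for the
equal-area circle), and at 300 kPa deflections are tens of millimetres.
Real membranes would stiffen geometrically (membrane stress) long before
that; the model deliberately stays linear, mirroring the linear-elastic
setting it reduces, so ratios, orderings and timing — not absolute
large-load deflections — are the physically meaningful outputs.

## The transient integrator

Implicit trapezoidal rule on the two-state system, fixed step
$dt = 10^{-5}$ s (the guard requires $dt \le T/100$). The scheme is
A-stable and time-reversible; for this linear system each step is one
pre-factored 2×2 solve, so a 25 ms window costs 2 500 steps and the full
48-run sweep stays under a second. Three structural checks are built in and
tested: cumulative inflow equals displaced volume to well below 0.1% (the
trapezoidal update of $V$ *is* the trapezoidal quadrature of the stored $q$
series); halving $dt$ moves peaks by far less than 0.1%; and post-pulse
energy $\tfrac12 L_h q^2 + V^2/2C$ must not grow (an integration-blow-up
guard that aborts with advice to reduce `dt`). Peak metrics take the argmax
of the sampled series; ties resolve to the earliest sample; an all-zero
response flags the lag `"undefined"`, and a response still rising at the end
of the window (step loads) flags `"non-pulse"`.

## Design choices that were genuinely open

* **Width definition** — maximal chord of the perpendicular cross-section;
  chosen because it is rotation-invariant and matches what a reader of an
  axial CT slice would maximise; documented in `measure_va_widths()`.
* **Inner-opening width** — never reported by CT protocols; set equal to the
  midpoint width, making the duct cylindrical over its inner half. Only
  $\int r^{-4} ds$-type integrals would change under another choice, and the
  effective-radius reduction uses the midpoint calibre as the bottleneck.
* **Cross-section shape** — circular with diameter equal to the local
  width: the single-parameter choice consistent with a one-number CT
  measurement.
* **Plate vs shell/solid membrane** — thin clamped plate; the RWM span/
  thickness ratio (~30) is within plate territory and the closed forms give
  oracles the solver must hit.
* **Static membrane inside the transient loop** — the membrane's own
  inertia is negligible at 60 µm × 2 mm² scale; its dynamics are carried by
  the hydraulic compliance, with `zeta_add` standing in for unmodelled
  distributed losses (see above).
* **Lumped damping default `zeta_add = 1`** — see the parameters section;
  the undamped reduction is available but demonstrably inverts the calibre
  trends and violates pressure limiting, which is why critical damping is
  the study condition.

## Known limitations

* No full 3D fluid–structure interaction: wave propagation inside the
  labyrinth, spatial pressure gradients and added-mass effects are all
  collapsed into $(R, L_h, C, \zeta)$. Quantitative peak values published
  for patient-specific 3D geometry are out of reach by design; the package
  asserts orderings, ratios and timing.
* Endolymph and perilymph are one incompressible fluid; the membranous
  labyrinth is not resolved (`alpha` is the knob that acknowledges this).
* Linear elasticity throughout; no large-deflection stiffening, no rupture
  criterion.
* The laminar reduction is justified at physiological velocities; at the
  highest loads the peak duct Reynolds number exceeds 2000 and `report()`
  flags those runs as formally outside the laminar assumption.
* The phantom is schematic anatomy on a clean grid: it validates the
  measurement pipeline, not clinical segmentation.

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use: phantoms at 0.05–0.2 mm spacing
(grids up to ~340 × 165 × 110 voxels), plate solves at element sizes from
1 mm down to a/20 ≈ 0.04 mm (basis degree 2–10, ≤ 365 report nodes), and
transients at $dt = 10^{-5}$ s over 25 ms (2 501 samples), 48 runs per
sweep. These sizes were chosen so every check runs comfortably on a laptop
while leaving each estimator's error far below its asserted tolerance.
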