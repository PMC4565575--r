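---
title: "Modelling electrochemotherapy treatment plans with ectoplan"
author: "ectoplan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electrochemotherapy treatment plans with ectoplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectoplan)
```

## The planning problem

Electrochemotherapy (ECT) potentiates a poorly permeant cytotoxic drug
(bleomycin) by electroporating tumor cells: short high-voltage pulses
delivered between pairs of needle electrodes raise the local electric field
above the *reversible electroporation threshold*, transiently permeabilizing
cell membranes. For deep-seated head-and-neck tumors, rigid fixed-geometry
electrodes cannot reach the lesion, so individually inserted *single long
needle electrodes* (3 cm un-insulated active tips on an insulated shaft) are
used. Treatment success then hinges on planning: electrode positions and
per-pair voltages must guarantee that the whole tumor plus a safety margin
of normal tissue (up to 5 mm) experiences a field above the reversible
threshold, while needles avoid vessels and bone and every pulse stays within
the generator's current limit.

`ectoplan` implements that planning pipeline on synthetic voxel anatomy:
phantom generation, electrode-array modelling, a nonlinear electrostatic
field solver with electroporation-dependent conductivity, coverage and
robustness analysis, position/voltage optimization, navigation export, and
the current-prediction QA arithmetic used to validate plans against
pulse-generator readings.

## Field model

For each electrode pair the package solves the electrostatic continuity
equation

$$\nabla \cdot \big(\sigma(|\mathbf E|)\, \nabla \varphi\big) = 0,$$

with the pulse voltage imposed on the anode's active tip, 0 V on the
cathode's, and an insulating outer boundary (the body far from the
electrodes carries negligible current; fixtures pad the grid so the boundary
is at least 1.5 array diameters from any electrode). Tissue conductivity
depends on the local field through electroporation: below the reversible
threshold `e_rev` it is the baseline `sigma0`; above the irreversible
threshold `e_irrev` it saturates at `sigma0 * sigma_factor`; in between the
package uses a smooth raised-cosine ramp (a linear ramp is available). The
coupled problem is solved by damped fixed-point iteration (damping 0.5)
until the predicted current changes by less than `fpTol` (default 1e-3)
between iterations.

### Discretization

The grid is the phantom's voxel grid: 7-point finite differences with
harmonic-mean face conductivities, which is robust across the discontinuous
conductivity at tissue boundaries. The linear systems are solved with
Jacobi-preconditioned conjugate gradients on the stencil, warm-started
across fixed-point iterations; intermediate solves inside the fixed point
use a looser residual (1e-4, ample for a 1e-3 current tolerance) and the
reported solution is polished to a relative residual of 1e-8.
Deterministic throughout — no randomized preconditioning.

Needle electrodes are thinner than, or comparable to, the voxel size, so a
naive "paint the voxels and fix their potential" boundary treatment
misrepresents the conductor: the rasterized voxel set behaves like a
cylinder of a grid- and alignment-dependent effective radius rather than the
physical one, and the predicted current inherits that bias. `ectoplan`
instead uses the thin-conductor coupling familiar from well models in
subsurface flow simulation: electrode voxels carry metal conductivity (the
needle interior is equipotential) and each is tied to the applied potential
through a radial series conductance per unit active length,

$$g = \frac{2\pi\,\sigma_{\text{local}}}{\ln(r_{\text{eff}}/r_w)},$$

which converts the lattice's per-unit-length conductance into that of a true
cylinder of the physical radius $r_w$. The effective radius
$r_{\text{eff}}$ of the rasterized cross-section is measured once per
electrode from a small 2-D lattice solve that mirrors the 3-D cross-section
(same transverse spacings, same axis offset within the cell, same inclusion
rule, metal interior); it is recovered by fitting the logarithmic far field
over a mid-range annulus, which is insensitive to the model's outer
boundary. If the node set under-represents the needle
($r_{\text{eff}} < r_w$), the inclusion radius is grown until it
over-represents and the series term dials it back. In the package's tests
this keeps the predicted current of the two-needle validation fixture
stable to within 3% when the grid is refined from 1.0 mm to 0.5 mm.

Two further geometry choices matter at the needle ends: the *insulated
shaft* above the active tip is modelled as non-conductive voxels (the
clinical rationale for partially insulated needles is precisely that the
shaft shields the normal tissue it passes through), and the active tip has a
flat proximal face where it meets the shaft — only the distal tip carries a
rounded cap. Needles of the array that are not part of the currently pulsed
pair are not modelled (no floating-conductor constraint); this follows
common ECT modelling practice, where the perturbation from inactive thin
needles is small compared with tissue-property uncertainty.

The predicted pair current is the total coupling flux out of the energized
electrode; the anode/cathode flux mismatch (`currentBalance()`) is a
discrete conservation check and stays far below 1% on converged solves.

### Validation against a closed form

The solver is validated against the two-cylinder conductance per unit
length, $G/L = \pi\sigma / \operatorname{arccosh}(d/2a)$, on a homogeneous
fixture (two parallel needles, radius 0.5 mm, separation 10 mm, active
length 30 mm, electroporation disabled). Two physical effects bracket the
comparison and are worth understanding when reading the test: the closed
form describes *infinitely long* cylinders in an *infinite* medium, so
finite rods carry more current (end fringing; an independent
method-of-moments computation puts this at roughly +15% for this geometry),
while the insulating simulation boundary suppresses part of it. The
agreement asserted in the acceptance suite (within 10% at 0.5 mm spacing)
is therefore a joint check of discretization and boundary policy, not a
pure discretization-error bound.

## Tissue parameters

The phantom knows four tissue classes. Defaults (all configurable through
`tissueTable()`):

| tissue | sigma0 (S/m) | sigma_factor | e_rev (V/cm) | e_irrev (V/cm) |
|--------|-------------:|-------------:|-------------:|---------------:|
| normal soft tissue | 0.2 | 3.5 | 350 | 800 |
| tumor | 0.3 | 3.5 | 400 | 800 |
| vessel (blood) | 0.7 | 3.5 | 350 | 800 |
| bone | 0.02 | 1.0 | 350 | 800 |

The thresholds adopt the display convention of clinical field-coverage maps
for 8 x 100 µs pulses (tumor shown covered above 400 V/cm, normal tissue
above 350 V/cm); conductivities are representative literature-range values.
These are package assumptions, not measured patient values — the clinical
workflow this emulates cites tissue-property libraries that are not
reproduced here, and current-prediction errors of tens of percent (see the
packaged QA table) are expected when assumed conductivities meet real,
previously irradiated tissue.

## The star array and schedule

`starArray()` builds the 5-needle configuration used clinically for
~2 cm lesions: a central needle in the tumor and four peripheral needles on
a square 10 mm from it (adjacent peripherals then sit 14 mm apart — the clinical
1 cm / 1.4 cm pattern), all parallel, with 3 cm active tips centred
on the target depth. `starSchedule()` delivers the four adjacent
outer–outer pairs at 1200 V followed by the four center–outer pairs at
1000 V, 8 pulses of 100 µs per pair — 64 pulses per lesion, at roughly
1000 V/cm voltage-to-distance ratio for the center–outer pairs. Generic
arrays and schedules are first-class (`electrodeArray()`,
`pulseSchedule()`); the star helpers are conveniences over them.

Coverage of a delivered sequence is the voxelwise *maximum* of the per-pair
field magnitudes: each pair permeabilizes what it reaches, and effects
accumulate. Pairs are solved independently by default; a
`persistentSigma` mode carries the electroporated conductivity forward
across pairs for users who want pulse-history memory, but it is off because
the clinical planning convention this mirrors does not state such memory.
Coverage thresholds are inclusive (`>=`).

## Phantoms, margins, fixtures

`makePhantom()` builds labelled volumes from geometric solids with
voxel-center membership (deterministic and easy to check against
enumeration). Overlapping solids are a configuration error, not a
precedence rule. The safety margin is a spacing-aware Euclidean dilation
(exact 3-D distance transform in world mm, so anisotropic grids behave),
minus the tumor, restricted to normal tissue.

`ectCaseFixture()` reproduces the study-like case the package ships as its
default test-bed: a near-spherical ~20 mm lymph-node metastasis (20.3 mm
for lesion 1, 20.6 mm for lesion 2) at 0.57 mm native pixel size, a 4 mm
vessel cylinder whose wall lies 8 mm from the tumor surface, a bone slab at
the far edge, the star array and the clinical schedule. The vessel and bone
placement is synthetic — the real anatomy is patient-specific and
unavailable — and is chosen so that a naively shifted trajectory collides
with the vessel, exercising the collision checks. What passing tests on
these phantoms show is that the *pipeline* is correct (geometry, solver,
aggregation, arithmetic); they cannot show that real, irregular, previously
irradiated anatomy is predicted accurately — the packaged QA table, with
per-pair current errors between -17% and +58% against generator readings,
is the honest statement of that gap.

Analyses in this vignette and the test suite run the case fixture at
1–2 mm spacing rather than the native 0.57 mm; 1 mm keeps a full 8-pair
nonlinear solve within minutes on a laptop core while resolving the 20 mm
lesion with ~4,200 voxels, which is ample for coverage fractions. The
electrode boundary treatment above makes currents nearly
spacing-independent, which is what licenses the coarser default.

## Optimization

`optimizePlan()` searches over the star center (within 5 mm of the tumor
centroid), insertion direction (a cone), tip depth, and the two voltage
levels (bounds 500–1500 V, 50 V steps in the descent stage; both
configurable). The objective is

`score = 1.0 * tumor_coverage(e_rev) + 0.5 * margin_coverage(e_rev) - 0.5 * overreach`,

where overreach is the fraction of non-margin normal tissue at or above the
irreversible threshold — rewarding complete reversible coverage of the
target while penalizing ablative exposure of uninvolved tissue. Candidates
violating constraints (vessel/bone collision, raster outside the grid,
predicted current above the 50 A device cap) are discarded. The search is
deliberately transparent: exhaustive enumeration when the discrete
candidate set fits the budget, a seeded sample otherwise, then coordinate
descent; ties break lexicographically (higher tumor coverage, lower
overreach, lower total voltage). Scoring runs on a 2x coarsened grid for
speed and the winner is re-scored at full resolution; both scores are
returned. Robustness is *reported* (`robustnessSweep()`), not optimized:
whether robustness belonged in the original clinical objective is not
stated in the sources this design follows, so the package keeps the
objective interpretable and surfaces robustness alongside it.

`robustnessSweep()` perturbs each electrode by an independent
uniform-in-sphere shift (default radius 1 mm — the navigation literature
reports ~1 mm guidance accuracy) and scales each tissue's baseline
conductivity by ±20%, re-solves, and reports min/mean/max tumor coverage
over a seeded 20-member ensemble.

## Navigation export

`markTrajectories()` reproduces the hand-off used with optical navigation:
entry and tip of every needle are marked in a copy of the planning volume
by setting the containing voxel to 3000 (a value far outside soft-tissue
intensities), one voxel per marker. Because the guidance system controls
entry point and angle but not depth, planned insertion lengths are exported
per electrode for ruler verification. `placementError()` quantifies
achieved-vs-planned placement as the 3-D point-to-line distance in mm and
in planning-image pixels (0.57 mm pixels make a 2-pixel deviation 1.14 mm);
the in-plane vs 3-D ambiguity of pixel-denominated errors is resolved here
as 3-D distance divided by the isotropic in-plane pixel size.

## Numerical choices and degenerate inputs

* Voxel membership, coverage thresholds and rasterization radii are
  inclusive; ties at exact boundaries (a world point on a voxel face) are
  resolved by `floor`, matching the marker-voxel convention.
* Zero applied voltage short-circuits the solve to the exact zero field.
* A fixed point that fails to converge in `fpMaxit` iterations raises an
  error carrying the last relative current change; `allowUnconverged`
  downgrades this for diagnostic runs.
* Empty masks (coverage of nothing) and degenerate trajectories
  (entry = tip) are errors, not NaNs.
* All randomness (optimizer sampling, robustness ensembles) flows through
  explicit integer seeds; re-running with the same seed is bit-identical.
* Grid coarsening keeps retained voxel centers at their world positions, so
  masks generated before and after coarsening refer to the same anatomy.
* Collision checks test needle-to-voxel-center distance, consistent with
  the phantom's membership rule; on grids much coarser than the needle
  radius a trajectory can slip between voxel centers, so collision
  screening should run at (or near) the phantom's native resolution rather
  than on a coarsened copy.

## Limitations

The package models quasi-static per-pulse fields: no transient membrane
dynamics, no Joule heating, no electrode-tissue contact impedance, no
cardiac-synchronization timing. Volumes are axis-aligned (no orientation
matrices); NIfTI is the only volume format. Segmentation of real images is
out of scope — phantoms stand in for it. Current predictions inherit the
assumed conductivities; the packaged QA table shows what that meant against
a real pulse generator.
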