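---
title: "Methods: axisymmetric FE evaluation of bilayer dental implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axisymmetric FE evaluation of bilayer dental implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantFE)
```

## The model

The package evaluates the load transfer between a dental implant and a
mandibular bone segment under a static axial bite force. Two implant
families are modeled: a conventional solid Ti6Al4V fixture, and a bilayer
fixture whose outer shell of thickness $T_L \in \{1, 1.5, 2\}$ mm is a
porous HA/Ti composite around a solid Ti6Al4V core (core diameter
$6 - 2T_L$ mm). All materials are homogeneous, isotropic and linearly
elastic; all interfaces (core–shell, implant–bone, cap–implant) are
perfectly bonded, representing complete osseointegration. The load case is
a 250 N axial compression applied as a uniform traction over the top of
the ceramic cap, with the lateral bone surface fully fixed.

### Shell homogenization

The shell stiffness is bracketed by the rule of mixtures. For volume
fractions $V_{HA} + V_{Ti} = 1$,

$$E_{\max} = E_{Ti} V_{Ti} + E_{HA} V_{HA}, \qquad
  \frac{1}{E_{\min}} = \frac{V_{Ti}}{E_{Ti}} + \frac{V_{HA}}{E_{HA}},$$

and, with porosity fraction $p$ degrading only the titanium skeleton,

$$E_{\max}^{(p)} = V_{HA} E_{HA} + V_{Ti} E_{Ti} (1 - p), \qquad
  E_{\min}^{(p)} = \left( \frac{V_{HA}}{E_{HA}} +
  \frac{V_{Ti}}{E_{Ti}(1-p)} \right)^{-1}.$$

Pore geometry is deliberately not resolved — no Gibson–Ashby or
Mori–Tanaka micromechanics — because the design sweep treats the two
bounds as the uncertainty envelope of the true porous-composite stiffness.
Porosity of 100 % is excluded (the Reuss titanium term diverges). The
published reference table for this design family contains cells that are
inconsistent with these rules (its porous upper-bound column for all but
the first row matches the rule evaluated with $p$ equal to the HA
fraction rather than the row's printed porosity, and one dense
lower-bound cell is an evident typo); `build_material_table()` always
computes from the rules at the row's stated porosity and *flags* the
inconsistent reference cells in its `reference_mismatch` attribute rather
than reproducing them.

### Material constants

All moduli are stored in MPa (mm–N–MPa unit system throughout); the bound
functions accept GPa via `units = "GPa"`.

| region | E (MPa) | nu | note |
|---|---|---|---|
| cortical bone | 13 000 | 0.30 | |
| trabecular bone | 1 370 | 0.30 | |
| Ti6Al4V core / conventional | 120 000 | 0.35 | |
| ceramic cap | 68 900 | 0.28 | |
| shell | from the bounds | 0.30 | see below |
| phases: Ti / HA | 120 000 / 70 000 | — | mixture inputs |

The Poisson ratio of the homogenized shell is not determined by the
mixture rule; the default 0.30 lies between titanium (0.35) and typical
hydroxyapatite (≈0.27). In a linear model its influence is bounded and
smooth; it is exposed (`material_constants()`, YAML override via
`load_constants_config()`) rather than hidden.

## Geometry idealization — what the generator emulates

The mesh generator is the pipeline's synthetic-data stage: every input is
built from printed dimensions, no external geometry files exist.

The 3D assembly (rectangular bone block, helically threaded implant) is
reduced to a **2D axisymmetric half-section**: the bone becomes a cylinder
of radius 8.15 mm (half the block width) with a 2 mm cortical band on the
crestal and outer lateral surfaces, and the helical thread becomes a stack
of 13 axisymmetric annular fins (depth 1 mm, pitch 1 mm, symmetric
triangular profile, so the flanks rise 1 mm radially per half pitch).
Choices the source dimensions do not determine, and their defaults:

* **Cap**: shape unspecified; a cylinder, 6 mm diameter × 2 mm tall,
  bonded to the implant platform only (configurable in `bone_spec()`).
* **Cortical band on the bottom surface**: off by default
  (`cortical_bottom`), since only crestal and lateral coverage is stated.
* **Bottom boundary condition**: free by default; only the lateral
  surface is stated as fixed. A roller/fixed bottom can be added through
  `load_case()` tags.
* **Thread profile**: symmetric triangle with base equal to the pitch
  (adjacent fins meet at the root); a thread-less profile
  (`threads = FALSE`) is available for convergence studies.

Meshing uses 6-node quadratic triangles (mirroring the quadratic
tetrahedra customary for such models) on a tensor-product grid whose lines
sit on every material radius and height; in the thread band the cells have
exactly the 2:1 radial:axial aspect ratio of the fin flanks, so the
zig-zag interface coincides with cell diagonals. Consequences that the
tests rely on: per-region mesh areas equal the analytic areas *exactly*
(not just in the limit), every interface edge separates exactly one
implant-side and one bone-side element, and generation is fully
deterministic — the `seed` argument exists for interface stability and is
ignored.

What the generator does **not** emulate: helical (non-axisymmetric) thread
geometry and lateral loading, anatomic bone shape and density gradients
from imaging, and any contact nonlinearity (the bonded interface is exact
by construction). Passing tests therefore demonstrate correctness of the
solver and pipeline on the idealized geometry, not fidelity to any
particular patient anatomy.

## Solver numerics

* Strain ordering $(\varepsilon_{rr}, \varepsilon_{zz},
  \varepsilon_{\theta\theta}, \gamma_{rz})$ with engineering shear; dofs
  interleaved per node; compression negative internally, magnitudes
  reported.
* Element stiffness integrated with the 7-point (degree-5) symmetric
  triangle rule; all points are interior, so the hoop term $N_i/r$ is
  never evaluated on the axis. Nodes on the axis carry the essential
  condition $u_r = 0$.
* The axial load is a uniform traction over the tagged surface with
  consistent (quadratic) nodal forces integrating exactly to the total
  force — a point load would add an artificial singularity.
* Direct sparse Cholesky factorization (Matrix); results are
  deterministic for a fixed mesh. Because stiffness is linear in Young's
  modulus at fixed Poisson ratio, `precompute_stiffness()` caches
  unit-modulus region matrices; a design sweep then only rescales and
  refactors, which is what makes the 109-configuration study run in
  about a minute.
* Stress/strain recovery: element fields are evaluated at the element
  nodes and averaged per node **within each region only** — averaging
  across material boundaries would smear the interface discontinuity that
  the study's metrics live on. For straight-sided quadratic triangles
  this equals linear extrapolation from the interior integration points.
  At axis nodes the hoop strain uses its limit
  $\varepsilon_{\theta\theta} \to \varepsilon_{rr}$.
* Verification oracles (all in the test suite): the axisymmetric patch
  test ($u_r = ar$, $u_z = bz + c$) to machine precision on a jittered
  mesh — note that a uniform *shear* state is not an equilibrium state in
  axisymmetry and is excluded on purpose; the uniaxial bar
  ($\sigma_{zz} = -F/A$, ≤0.1 %); bonded concentric cylinders, whose
  stiffness-weighted load partition
  $\sigma_i = E_i F / \sum_j E_j A_j$ is checked at the supported plane
  (≤0.5 %) because with a large modulus contrast the shear-lag
  development length exceeds the cylinder height, so mid-height values
  still carry end effects; and a global axial equilibrium audit
  (residual ≤ $10^{-6} F$) on every solve.

### Strain scalarization

Scalar "interfacial strain" is reported as the von-Mises-type equivalent
strain with the material's own Poisson ratio as the effective ratio,

$$\varepsilon_{eq} = \frac{1}{1+\nu}
  \sqrt{\tfrac12\left[(\varepsilon_{rr}-\varepsilon_{zz})^2 +
  (\varepsilon_{zz}-\varepsilon_{\theta\theta})^2 +
  (\varepsilon_{\theta\theta}-\varepsilon_{rr})^2\right] +
  \tfrac34\gamma_{rz}^2},$$

normalized so a uniaxial stress state returns its axial strain — the
convention of mainstream commercial codes. Maximum absolute principal
strain is available behind `method = "max_principal"` because the choice
materially affects microstrain comparisons. The headline metric is the
maximum over the **cancellous (trabecular) side** of the tagged interface
(the crestal cortical side can be included via `bone_regions`); because
thread-root corners are singular in linear elasticity and a raw maximum is
mesh-sensitive, the 99th percentile of the same nodal values is always
co-reported.

## Mechanostat windows and design selection

Microstrain classifies into half-open windows $[\ell, u)$: disuse below
100 µε (this lower threshold is not part of the reported windows; 100 µε
is the conventional default and is configurable), adapted to 1 500 µε,
mild overload to 4 000 µε — with its lower part up to 2 500 µε flagged as
the most desirable range for peri-implant bone — and pathologic overload
above. A value exactly on a threshold belongs to the upper window; this
boundary convention is arbitrary but documented and tested.

`select_optimal()` formalizes a qualitative design preference as an
explicit lexicographic rule: feasibility (strain below the overload
threshold), then restriction to rows inside the desirable window when any
reach it, then maximal shell stress reduction, with ties broken by thicker
shell and then lower HA content. The tie-break order is this package's
own choice; every stage is configurable, and an empty feasible set is
reported rather than raised.

## Problem sizes

The production element size is 0.25 mm (half-section), giving roughly
10 000 quadratic triangles and 40 000 degrees of freedom per
configuration; the convergence ladder is 1 / 0.5 / 0.25 mm. The full
109-configuration sweep at production size completes in about 80 s on one
core, which is the scale the test suite and the acceptance script run at.

## Known limitations

* **Stiffness of the idealization.** Revolving the bone block into a
  cylinder turns the two fixed cut faces into a fixed ring 5.15 mm from
  the implant surface, all around. This load path is substantially
  stiffer than a 3D block with free buccal/lingual faces: the implant
  settles only a few micrometres under 250 N, so interfacial strains and
  peak stresses come out several-fold lower than three-dimensional
  simulations of the same assembly report. The package's acceptance
  checks therefore treat 3D reference magnitudes as directional context;
  the quantities the pipeline computes are internally verified instead
  (oracles above).
* **Singular corners.** The implant/cap/cortical junction at the crest
  and the thread roots are re-entrant bi-material corners; in linear
  elasticity the exact fields there are unbounded, so *maximum* nodal
  values keep growing under refinement and a fixed-percentage convergence
  gate on them is not attainable on corner-sharp geometry. This is why
  the percentile strain is co-reported and why peak values must be read
  as mesh-indexed (production size 0.25 mm) rather than converged-field
  quantities.
* The crest-corner peak stress is bearing-controlled: it varies only
  weakly with the shell modulus, so shell-stress *reductions* relative to
  the conventional implant are small in this idealization.
* Single static load case; no lateral/oblique bite forces, no fatigue,
  no bone heterogeneity or remodeling over time, no fluid effects.
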