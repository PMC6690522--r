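---
title: "Mass-spring-hinge mechanics of growing plant tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-spring-hinge mechanics of growing plant tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phytomech)
```

## The model

Growing plant tissue is modelled as a two-dimensional square lattice of
mass points under the plane-stress idealization: the epidermal cell wall
acts as a thin, tension-stressed skin, so all loads act in the plane and
moduli carry thickness-integrated units (MPa·m). Neighbouring points are
joined by springs along the two principal cellulose fibre directions; every
unit-cell corner carries a hinge, an angular spring penalizing deviation of
the two arms from orthogonality. This layout mirrors the orthogonal
microfibril architecture of polarized plant cells and makes the two fibre
directions independently stiff.

The constitutive target is a generalized orthotropic Hooke's law. Under
plane stress the Lamé parameters of each fibre direction follow from the
directional Young's modulus and a shared Poisson ratio,
$\lambda_i = Y_i\nu/(1-\nu^2)$, $\mu_i = Y_i/(2(1+\nu))$, and the shear
modulus convention is the mean $2\mu = \mu_x + \mu_y$. Matching the elastic
energy of one unit cell (resting lengths $x_0$, $y_0$, aspect $h=y_0/x_0$,
metric $s$, shear factor $\tilde s = s/(1+s^2)$, current area $A$) to the
continuum energy density yields the five non-zero stiffness components
listed in `?stiffness_components`; all strain measures are built from
spring length changes and inter-spring angles, so the model is frame
indifferent by construction (a Biot-type strain).

Forces on a mass point are assembled per point:

* **direct + Poisson terms** for each incident spring, with the
  cross-strain taken as the mean strain of the point's perpendicular
  springs and the mean of their resting lengths entering the stiffness
  component;
* **hinge shear** summed over the point's adjacent hinges (4 interior, 2
  border, 1 corner), each hinge contributing through its shear strain
  $\tau_n = \tan\varphi_n$, parallelogram area $A_n$, and rest geometry;
* **turgor**, the exact gradient of $-A_t\,p_t$ where $A_t$ is the shoelace
  area of the boundary polygon — border points only, with zero net force
  and torque on any closed boundary;
* **viscous drag** $-\eta\,\dot{\mathbf{x}}$, a purely numerical device.

Elastostatics is assumed throughout: growth is slow compared to the elastic
response, so every growth step is followed by damped Verlet relaxation to
equilibrium, and the mass and damping constants have no physical meaning.

### The sign of the point shear

The point shear strain (the mean of the adjacent hinge
strains) is sign-ambiguous on its own: adjacent corners of a sheared
parallelogram have supplementary angles, so the *plain* mean of
$\tan\varphi_n$ over a point's four hinges vanishes identically for a
homogeneous simple shear. The measured point shear therefore carries a
quadrant sign, $+1$ for (right, up) and (left, down) hinge pairs, $-1$ for
the mixed pairs, which makes a positive simple shear read $\tau > 0$ at
every point. The force expression is unaffected: each hinge enters it
through the product $\tau_n\,\partial\tau_n/\partial\mathbf{x}$, which is
invariant under the sign convention.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `L0` | 1 | µm | initial spring resting length (lattice spacing) |
| `Yx`, `Yy` | 20–80 | MPa·m | directional Young's moduli (cell-wall range) |
| `nu` | 0.2 | — | Poisson ratio; the wall is partially compressible, `0 ≤ ν < 0.5` |
| `pt` | 0–1 | MPa·m | turgor pressure, constant across the tissue |
| `hgamma` | 0.01 | — | Verlet step (reference value) |
| `m` | 1 | µg | point mass (numerical only) |
| `eta` | 1 | N·hγ/µm | damping (numerical only) |
| `thr` | 0.05 | µN | convergence threshold on the per-point static force |
| `ht` | 1 | min | Euler step of the growth equation |
| `k_max` | ln(4/3)/60 | min⁻¹ | growth-rate bound (one third per hour) |

## Numerical choices

**Convergence.** Relaxation stops when the largest per-point resultant of
the *static* forces (viscous term excluded — it vanishes at equilibrium)
drops below `thr`, with two refinements found necessary in practice:

1. *Quiescence.* For large or soft specimens the damped dynamics passes
   through a creep regime where the static force is balanced by drag; the
   static residual alone can dip below threshold long before the
   configuration stops changing. Convergence therefore also requires the
   viscous force to be below threshold.
2. *Threshold scaling.* A per-point force criterion weakens with specimen
   size: a smooth strain-deficit profile of amplitude
   $\delta e \sim \mathrm{thr}\cdot N/(2S)$ (softest stiffness $S$, $N$
   spacings) passes it. `tuned_solver()` scales the threshold as
   $S_\mathrm{soft}/N$, and the virtual experiments additionally scale it
   with the applied load level so that small probe loads are resolved to
   about 0.5% relative strain accuracy.

Because the corner-local hinge force is not exactly the gradient of an
energy, a free-floating specimen can settle into a steady rigid creep in
which the static residual equals the drag and never reaches an arbitrarily
small threshold. The solver detects this geometric stall (spring lengths
constant to $10^{-8}$ µm over 1000 steps with a bounded residual) and
accepts the state: the deformation has converged even though the frame
drifts; rigid-body motion is removed afterwards.

**Damping and step size.** The defaults (`hγ = 0.01`, `η = 1`) are kept as
the reference contract, but they over-damp the slowest breathing mode of a
100 µm specimen by an order of magnitude. `tuned_solver()` picks
near-critical damping for the softest long-wavelength mode
($\eta \approx 2m\,\pi\sqrt{S_\mathrm{soft}/m}/N$, where the soft stiffness
includes the turgor-only shear stiffness $2p_t$ when hinges are disabled)
and a Verlet step a safe factor below the stability limit of the stiffest
mode. Equilibria are independent of these choices; the test suite verifies
this by varying mass and damping.

**Boundary-stress lumping.** A prescribed edge stress is converted to nodal
forces as a follower load (per *current* edge length, fixed direction).
Each point takes half of its incident boundary segments; the edge *end
points* take their single segment at full weight. The full corner weight is
deliberate: the lattice transmits boundary stress through all $N{+}1$
parallel spring lines, and the uniform per-point load is the exact natural
boundary load of an affinely strained lattice. With half-weight corners a
boundary layer forms at the loaded edge that refuses to contract laterally
and biases the effective Poisson ratio about 14% low; with full corner
weight the measured small-strain moduli converge to the continuum inputs
(the calibration criterion that adjudicates the choice).

**Degenerate inputs.** Collapsed hinges ($|\cos\varphi| \to 1$) raise an
error; meshes without hinges (chains) fall back to rest-geometry cell
areas; boundary points with a single perpendicular spring use "means of
one" for the cross-strain conventions.

## Growth and remeshing

Growth is plastic: the resting length of each spring is multiplied by
$1 + h_t\,k$ per Euler step, with the orientation's rate field evaluated at
the spring midpoint and bounded by `k_max`. The growth trigger for
remeshing compares *resting* length against $2L_0$ (deposition of new wall
material tracks plastic expansion, not the instantaneous elastic state; a
current-length trigger is available for sensitivity tests). A triggered
spring is split at its geometric midpoint with zero initial velocity; both
children inherit half the resting and half the current length, preserving
strain across the split. If the facing parallel spring of an adjacent cell
has also split, a transverse spring (resting length: mean of the flanking
perpendicular springs) reconnects the grid; otherwise the inserted point
remains a *loose point* with three neighbours. Loose points still carry
four hinge strains via an auxiliary point at the midpoint of the spring
between next-next neighbours, with the resting length of the left (missing
y-arm) or upper (missing x-arm) neighbour; no force acts on the auxiliary
point. Logical grid coordinates are fractional for inserted points, so
spring orientation and the facing-spring lookup stay well defined through
repeated remeshing; point ids are never reused.

## What the virtual experiments emulate — and what they do not

The characterization suite is virtual rheometry on synthetic, initially
rectangular specimens: uniaxial tension (one border restrained to a line,
normal stress on the opposite border), pure shear (equal tangential
tractions on all four walls), a rotating point force at the center of a
boundary-fixed specimen, and growth-drift runs that change the cell metric
without remeshing. These probe the *model's* material behaviour — secant
moduli from the turgid prestate, measured on interior springs/points to
suppress clamp artifacts. They do not emulate real-tissue heterogeneity,
nonlinear wall rheology, strain-history-dependent stiffness, wall rupture,
or any hormonal/gene-regulatory feedback; passing them shows that the
lattice approximates the intended orthotropic Hooke material and how that
approximation degrades with strain, turgor, anisotropy and growth — not
that real tissue behaves this way.

Known quantitative behaviour, measured by `scripts/acceptance.R` and the
test suite on 60–100 µm specimens:

* small-stress limits converge to the inputs ($Y$, $\nu$, $\mu$);
* the neglect of the cell-area derivatives in the force assembly stiffens
  the response at finite strain — with the current-area convention used
  here, homogeneous-deformation analysis predicts
  $Y_\mathrm{eff} \approx Y(1-\nu e)(1+e)^2$, about $+10\%$ at 5% strain;
* turgor stiffens the moduli (exactly $2p_t$ on the hinge-free shear
  modulus; about $4p_t$ on the Young modulus, reduced by anisotropy);
* growth that changes the cell metric leaves the direct moduli nearly
  unchanged but drifts the shear response, because the hinge force of the
  published form scales as $(1+s^2)/(2s)$ relative to the energy-consistent
  force at metric $s$ — a documented model artifact that also breaks the
  isotropy of the point-force response in grown media.

## Scenario design

The two bundled scenarios illustrate emergent growth mechanics. The *root*
scenario (76 × 32 µm, $Y_x = 40$, $Y_y = 80$ MPa·m, $\nu = 0.2$,
$p_t = 0.2$ MPa·m, 141 min) grows only along x with a rate increasing
linearly from one quarter of `k_max` at the bottom border to `k_max` at the
top; the growth asymmetry bends the slab with the slow side on the inner
arc, and the shear field is antisymmetric about the vertical mid-line. The
*leaf* scenario (76 × 67 µm) grows in both directions with the same graded
profile. The linear-gradient fields and their amplitudes are this package's
design choice — published figures show such fields only as colour maps — so
the scenarios' contract is qualitative (bending sign, mirror antisymmetry,
residual-strain emergence, remeshing continuity), not a reproduction of
specific magnitudes.

## Problem sizes used in verification

The bundled verification runs use 100 µm specimens for the turgor-shear
oracle, the small-strain limits and the stress sweeps, and 60 µm specimens
at 16 force angles for the rotating-force protocols and growth-drift runs
(the bulk moduli are intensive; doubling the specimen changes the sweep
results only through $\mathcal{O}(1/N)$ boundary terms). The test suite
runs the same protocols at 60–80 µm and property checks on meshes of a few
cells.

## Known limitations

* The hinge force follows the published per-corner form, which is not an
  exact energy gradient: its arm-point reactions are omitted, it sustains
  the rigid-creep steady state described above, and its shear stiffness
  drifts with the cell metric under anisotropic growth.
* Plastic shear growth is not representable (growth acts on the two
  resting lengths only), and mass points are never removed (no wall
  rupture).
* In the presence of large shear the fibre frame is skewed and the Poisson
  coupling is no longer exactly orthogonal to the applied stress.
* Triangular/hexagonal lattices, 3D meshes and per-cell compartments are
  out of scope; the lattice is a wall-material continuum proxy.
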