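---
title: "Poroelastic modelling of cervical dilation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poroelastic modelling of cervical dilation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cervodil)
```

## The model

Cervical stroma is treated as a water-saturated porous deformable medium:
a linear-elastic drained skeleton (Young's modulus $E$, Poisson ratio
$\nu$) permeated by a compressible pore fluid that flows according to
Darcy's law with permeability coefficient $k$ (units
$\mathrm{m^4/(N\,s)}$, so $\mathbf q = -k \nabla p$ directly). Three
fields are carried as nodal unknowns on a bilinear quadrilateral mesh:
the solid displacement $\mathbf u$, the pore pressure $p$ (positive in
compression) and the Darcy velocity $\mathbf q$ — five degrees of
freedom per node in 2-D. The coupled balance equations are

* **mixture momentum**
  $\rho\,\ddot{\mathbf u} + \rho_f\,\dot{\mathbf q}
   = \nabla\!\cdot(\boldsymbol\sigma' - p\,\mathbf I) + \mathbf t$,
  with mixture density $\rho = (1-n)\rho_s + n\rho_f$, porosity $n$, and
  effective (skeleton) stress $\boldsymbol\sigma'$;
* **fluid mass balance**
  $\nabla\!\cdot\dot{\mathbf u} + n c_f\,\dot p + \nabla\!\cdot\mathbf q = 0$,
  with fluid compressibility $c_f$;
* **generalised Darcy law**
  $\rho_f\,\ddot{\mathbf u} + \tfrac{\rho_f}{n}\,\dot{\mathbf q}
   + \nabla p + \tfrac{1}{k}\,\mathbf q = \mathbf 0$.

Element-level Galerkin discretisation produces the block system with
mass ($m_{uu}, m_{qu}$), damping ($c_{uq}, c_{pu}, c_{pp}, c_{qq}$) and
stiffness ($k_{uu}, k_{up}, k_{pq}, k_{qp}, k_{qq}$) blocks that
`element_matrices()` evaluates by Gauss quadrature (2×2 by default).
The continuity and Darcy rows are weighted pointwise (no integration by
parts), so pressure boundary conditions are essential conditions on $p$
and flux conditions are essential conditions on $\mathbf q\cdot\mathbf n$;
on curved surfaces the latter are imposed through an orthogonal nodal
rotation onto the local normal. Surface pressures become work-equivalent
nodal forces on the loaded edges.

Assumptions worth keeping in mind: small strains and linear kinematics
(the model is exactly linear in the applied load), isotropy, full
saturation, no dilator–tissue contact mechanics (the dilator acts as a
prescribed uniform pressure, or optionally as a prescribed radial
opening), and 2-D plane strain on the tube cross-section (axial
variation neglected; the half model exploits mirror symmetry).

## Time integration

An implicit Newmark scheme advances the system with the balance
equations enforced at the end of each step; displacements follow the
full Newmark relations and the first-order fields $p, \mathbf q$ the
matching generalised trapezoidal rule with the same $\gamma$. One sparse
LU factorisation of the effective matrix (two-sided equilibrated, with
iterative refinement to a backward error of `linear_tolerance`) is
reused for all steps.

Defaults are $\Delta t = 0.1\,$s over 60 s and the trapezoidal pair
$\beta = 1/4, \gamma = 1/2$, which is non-dissipative: the
single-degree-of-freedom reference in `sdof_newmark_reference()`
conserves amplitude to 0.1 % and has a period error of
$(\omega\Delta t)^2/12 \approx 0.03\,\%$ at 100 steps per cycle.

Two practical refinements are used by the *scenario* configurations
(`dilation_config()`, the benchmarks), both standard for step-like
loads:

* **algorithmic damping** ($\gamma = 0.75$, $\beta = (\gamma+1/2)^2/4$,
  or the fully damped $\gamma = 1$ member in the consolidation
  benchmark). A sudden dilator load excites poroelastic waves with
  microsecond periods that a 0.1-s step cannot resolve; the
  non-dissipative member lets them ring indefinitely (bounded but
  polluting), while $\gamma > 1/2$ annihilates them within a few steps
  and perturbs the second-scale consolidation response only at
  $O((\gamma - \tfrac12)\Delta t)$;
* **a substepped first increment** (`startup_substeps`): an implicit
  step smears a load applied at $t = 0^+$ across the first increment,
  shifting the early consolidation response by a fraction of
  $\Delta t$; subdividing only the first step removes this at
  negligible cost.

## Verification oracles

The finite-element core is verified against independent closed forms
(none of which call the element code):

* **Terzaghi consolidation** (`terzaghi_pressure()`): a one-element-wide,
  40-element column under a step load with a drained top. The benchmark
  uses $c_v = 0.0625\ \mathrm{m^2/s}$ on a 1-m column so the time factor
  reaches 0.5 within 8 s of simulated time; the computed pore pressure
  tracks the Fourier series within about 0.7 % of the applied load from
  the sixth step on (tolerance 2 %).
* **Lamé thick-walled cylinder** (`lame_thick_cylinder()`): with the
  permeability scaled by $10^6$ the annulus drains freely and a slow
  pressure ramp reproduces the plane-strain solution; at 64×128 the
  radial displacement and centroid hoop stress agree to about 0.1 %,
  and uniform refinement shows an observed convergence order of about
  1.9–2.0 in the displacement $L_2$ error (bilinear elements).
* **Brute-force element oracle** (`element_matrices_bruteforce()`): an
  explicit scalar-loop re-derivation of every block, with quadrature
  nodes from `pracma`; agreement to $10^{-10}$ relative on randomised
  distorted quads. The comparison runs both routes at 4×4 Gauss points,
  since on distorted elements different quadrature orders legitimately
  differ by quadrature error.
* **Discrete conservation**: at every converged step the volume-integrated
  storage and divergence terms (computed by quadrature, via partition of
  unity) equal the consistent drainage flux recovered from the
  constrained pressure rows to the linear-solver accuracy
  (`mass_balance()`).

## Boundary-condition choices

The published study states the load (uniform pressure along the canal)
but neither the outer boundary condition nor the drainage surfaces, so
these are explicit configuration choices:

* `default_bc()` — outer surface **fixed and drained**, inner surface
  sealed (the balloon blocks the canal).
* `canal_bc(outer_fixed = FALSE)` — same drainage, but a
  **traction-free outer wall** (with the x-displacement pinned on the
  y axis to remove the rigid translation of the half model under its
  axisymmetric load). The scenario comparisons and the calibration use
  this variant.

The reason for the compliant variant is physical. With the calibrated
permeability ($k = 3\times10^{-15}\ \mathrm{m^4/(N\,s)}$) the
consolidation length over a one-minute procedure is
$\sqrt{c_v t}\approx 0.2$ mm — two percent of the wall thickness — so
the tissue responds almost undrained, i.e. nearly incompressibly. A
rigidly clamped outer wall then forbids essentially all displacement
(the response collapses to nanometres of storage compliance), the
opening becomes insensitive to $E$, and the peak effective stress is
dominated by the slowly growing drainage layer, so a step and a ramp to
the same pressure never converge within the procedure. A cervix embedded
in compliant pelvic tissue is better served by the traction-free outer
wall, under which the opening carries a strong deviatoric (stiffness)
signal, the two dilators' stresses agree to a few percent once their
pressures match, and — as the published comparison reports — the
step-loaded dilator stresses the tissue several-fold harder early in the
procedure.

## The equal-order element pair

All three fields share bilinear interpolation. In the nearly
incompressible undrained limit this pair can exhibit the classical
checkerboard pressure mode; the package ships an optional
Brezzi–Pitkäranta-type stabilisation (`pressure_stabilization` in
`solver_config()`, scaled by $\alpha h^2/\mu$, default **off**). The
drained and consolidating benchmarks do not need it (the Darcy terms
regularise the pair); the pure undrained-limit test enables it and shows
the interior pressure uniform to a fraction of a percent where the
unstabilised run checkerboards. It is left off by default because it
perturbs the continuity equation by a consistent $O(h^2)$ term that the
conservation audit would otherwise attribute to drainage.

## Calibration

`fit_parameters()` estimates $(E, k)$ by least squares on the mean
inner-surface radial opening (the published calibration equates balloon
fluid volume with canal opening), over $(\log E, \log k)$ so both stay
positive, with Levenberg–Marquardt (`minpack.lm`). The calibration
scenario is a 45-s ramp to 10 kPa held to 60 s on the default annulus,
coarsened to 8×16 with $\Delta t = 0.5\,$s inside the fitting loop.

Three deterministic safeguards stabilise the optimisation:

1. a **secant amplitude pre-match**: the opening is nearly inversely
   proportional to $E$, so one forward run rescales the stiffness guess
   onto the observed amplitude before the first iteration;
2. a **restart ladder in $k$** (×10, ×1, ×0.1 of the guess), keeping the
   branch with the smallest residual — the landscape contains a shallow
   spurious valley in which an exaggerated permeability plus inflated
   stiffness imitates the observed amplitude to a few tenths of a
   percent;
3. **plausibility bounds** ($E \in [10^4, 10^7]$ Pa,
   $k \in [10^{-17}, 10^{-13}]\ \mathrm{m^4/(N\,s)}$), two decades
   around reported soft-tissue values.

Identifiability deserves honesty: over one minute the response is
almost undrained, so the permeability enters only through the thin
outer drainage layer and its share of the opening signal is a few
percent. Noise-free synthetic data (an inverse-crime test: the same
mesh and step generate and fit) recover both parameters essentially
exactly; with 2 % observational noise the stiffness is recovered to
better than 1 % but the permeability only to a few tens of percent, and
data restricted to a drained steady state cannot constrain $k$ at all
(`opening_sensitivity()` demonstrates both regimes via the Gauss–Newton
normal-matrix eigenvalues). A calibration aiming at tighter permeability
bounds would need either a longer observation window or an observable
closer to the drainage physics.

## What the synthetic generator does and does not emulate

`synthesize_observation()` adds independent Gaussian noise to the
forward model's opening. It reproduces the *conditions* of the published
calibration — the ramp shape, duration, the calibrated parameter values
— but not the character of real measurements: balloon-volume-to-opening
conversion, smooth (autocorrelated) instrument drift, contact
nonlinearity at the balloon–tissue interface, or finite-strain
stiffening of real stroma. Passing the recovery tests therefore shows
the *estimator* is consistent and well-conditioned under the model's own
assumptions; it does not validate the constitutive model against tissue.

## Numerical choices, in brief

* SI units throughout; pressures in configuration files may carry
  explicit `Pa`/`kPa`/`MPa`/`bar` suffixes.
* Structured meshes with exact radial normals on the curved surfaces;
  all element Jacobians are checked positive at assembly.
* Sparse unsymmetric LU (`Matrix`), factor-once/solve-per-step,
  two-sided equilibration (the $u$, $p$ and $q$ equations differ by many
  orders of magnitude in natural scale), iterative refinement to a
  normwise backward error below $10^{-9}$ by default.
* Zero initial conditions (undeformed, unpressurised); consistent rates
  develop within the first (optionally substepped) increment.
* Default geometry $r_i = 1.5$ mm, $r_o = 10$ mm — the study does not
  state radii; these are configurable defaults chosen so a Hegar-type
  final radius of 4 mm remains within small-strain plausibility.
* Snapshot reporting uses the nearest recorded step and reports the
  offset; exports are fixed-precision ASCII, byte-stable across
  repeated runs.
* Problem sizes used by the shipped verification runs: 40-element
  column (consolidation), 64×128 half annulus plus an 8/16/32 radial
  refinement ladder (Lamé), 16×32 annulus at $\Delta t = 0.1$ s
  (dilator comparison), 8×16 annulus at $\Delta t = 0.5$ s (fitting
  loop).

## Known limitations

Small-strain linear kinematics (a Hegar dilation to 8 mm in a 3-mm
canal is far outside this regime — the comparison is meaningful for the
loading *protocols*, not the absolute late-time displacements);
isotropic homogeneous tissue with literature-default $\nu$, porosity,
densities and fluid compressibility; no contact, friction or insertion
mechanics; 2-D plane strain; equal-order interpolation with optional
rather than built-in pressure stabilisation; and a calibration
observable that constrains permeability only weakly at clinical time
scales, as discussed above.
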