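---
title: "Models and numerics of phagocytic cell spreading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics of phagocytic cell spreading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical picture

When an immune cell such as a neutrophil lands on a flat surface coated
with antibody, it spreads until its substrate-contact area reaches a
plateau ("frustrated phagocytosis").  Two competing explanations exist
for what drives the motion:

* **Brownian zipper** — passive short-range attraction between membrane
  receptors and surface ligands pulls the membrane down; the cell
  behaves like a very viscous droplet wetting a sticky surface.
* **Protrusive zipper** — active cytoskeletal protrusion pushes the
  membrane outward near the contact perimeter; adhesion only makes
  contact irreversible.

`phagospread` implements both, plus a discrete-adhesion refinement of
the second, inside one axisymmetric moving-boundary framework, so the
two hypotheses can be compared against the same measurements: the
contact-area-versus-time curve `A_c(t)`, its maximum slope (the
spreading speed), its plateau, and the early-phase power-law exponent.

## The mechanical model

The cell is a "cortical shell, liquid core" object: an axisymmetric
body of Newtonian fluid of constant volume (viscosity `mu` = 200 Pa s
passive, 1660 Pa s active), bounded by a cortex under isotropic tension.
At the low Reynolds numbers of cell spreading the flow obeys the Stokes
equations; on the free surface the fluid traction balances three
boundary stresses:

* **Cortical stress** `-tau H n` (Laplace), with `H` the mean curvature
  and `tau` a biphasic function of relative area expansion
  `x = A_cell / A_cell0`: `0.01 + 0.16 (x - 1)` mN/m up to the knee at
  `x = 1.26`, then `0.0516 + 0.545 (x - 1.26)` mN/m.  `A_cell` is the
  **total** surface area including the adherent disc — the cortex spans
  the whole cell, and the alternative (free surface only) would make the
  tension jump as contact grows.
* **Adhesion stress** (continuum variants): the surface integral of a
  7-4 pair potential of range `D0` = 50 nm over the substrate plane
  outside the current contact disc, attraction beyond `D0`, repulsion
  inside it.
* **Protrusion stress** (active variants): an outward normal stress
  concentrated at the contact perimeter, decaying as
  `exp(-(s_contact - s)/s0)` in arc length with `s0` = 0.8 um, with
  magnitude tied to the contact area: linear (`0.05 + 0.3 A_c/A_trans`)
  in the low-tension regime, square-root
  (`0.35 + 0.65 sqrt((A_c - A_trans)/120)`) in the high-tension regime,
  saturating at 3.5 kPa.

Adherent membrane obeys no-slip and never detaches (the "zipper").

## Design choices where the formulation was open

These are the package's own resolutions of points the constitutive
summary above does not fix; each is localised in one function and
covered by tests.

**Adhesion sign and normalisation.**  The 7-4 kernel is oriented so
that membrane farther than `D0` from a ligand is attracted toward it
and closer membrane is pushed back — a Lennard-Jones-like interaction
whose plane-integrated stress on flat membrane vanishes at the standoff
`h* = 2^(-1/3) D0` (about 40 nm).  The interaction plane is placed at
`-h*` so that resting membrane at `z = 0` is in equilibrium.  The
absolute interaction scale is never fixed by the constitutive data, so
the package exposes the single product `W_adh = sigma_0 rho_l D0^2`
(Pa) and calibrates its default so the peak attractive stress at 100%
relative ligand density is 2 kPa, comparable to the maximal protrusion
stress.  Everything downstream is linear in `W_adh`; relative-density
sweeps scale it.  The corresponding work of adhesion has the closed
form `gamma = (pi/2) 2^(1/3) W_adh D0` (about 183 uJ/m^2 at 100%),
which is the "effective adhesion energy" used in the Young-Dupre check.

**Contact capture height.**  Advected free membrane joins the adherent
set when it descends to the potential standoff `h*`: membrane that has
reached the potential minimum is adhered.  An earlier build captured at
half that height; the artificial repulsive barrier between standoff and
capture then stalled the contact line about 14% short of the
Young-Dupre equilibrium area.  With capture at the standoff the
simulated Brownian plateau agrees with the equilibrium prediction to a
few percent, which is the internal-consistency test of the whole
contact-line treatment.

**Young-Dupre convention.**  The equilibrium relation is
`gamma = tau (1 - cos theta_c)` with `theta_c` the wetting contact
angle: `theta_c -> 0` for a barely attached sphere (`gamma -> 0`) and
`theta_c -> pi` for a fully flattened cell (`gamma -> 2 tau`).  In cap
coordinates `theta_c` is the supplement of the polar half-angle.

**Transitional contact area.**  The protrusion law needs `A_c,trans`
(the contact area at which `A_cell` crosses `1.26 A_cell0`) before that
moment is reached.  It is precomputed from constant-volume spherical-cap
geometry (about 104.7 um^2 for the 8.5 um cell), once per run.

**Smoothing of the constitutive knees.**  The tension knee uses an
exact C1 quadratic junction over `ratio_trans +- smoothing_width`
(default 0.02 in area ratio).  The protrusion law blends its branches
with a smoothstep in area ratio, softens the square-root onset, and
saturates through a soft-min; with `smooth = FALSE` the raw printed
branches are evaluated (the unit anchors are asserted there).

**Membrane-fluctuation capture distance.**  The discrete model forms a
bond when free membrane approaches a ligand ring to within the RMS
thermal fluctuation height
`sqrt(kB T/(4 pi tau) ln(1 + tau A_cell/(pi^2 kappa_b)))`.  With
`T = 310 K` and `kappa_b = 2e-20 J` this gives 17.8 nm at resting
tension and about 2 nm at 1 mN/m, matching the published anchors; the
bending modulus sits at the low end of the plausible range and is a
configuration parameter.

**Protrusion clock.**  In the discrete model the protrusion stress
decays as `exp(-(t - t_bind)/t0)` with `t0` = 66 s, where `t_bind` is
the time of the *most recent* bond: every fresh bond re-triggers
signalling, and spreading stalls when the gap to the next free ring
cannot be crossed before the stress decays.  This single-clock reading
is what makes the maximum contact area density-dependent while leaving
the spreading speed almost density-independent.

## Numerical method

**Geometry.**  The cell surface is an ordered generating curve from the
apex to the contact line and on to the axis, with arc-length-graded
nodes packed toward the contact line.  Curvature comes from
moving-window cubic fits of the normal angle `phi(s)` (window 7), with
the on-axis singularity `sin(phi)/r` replaced by its symmetric limit.
After each step the free contour is smoothed by a 5-node local cubic
least-squares filter, re-sampled to the configured resolution, and
displaced uniformly along its normals (scalar root find) so the
enclosed volume returns to its initial value to 1e-6 relative.

**Mesh.**  A structured quadrilateral "fan": each free-surface node is
joined to a point on the symmetry axis at matched arc fraction; the
first transversal is exactly the adherent disc.  Layer thicknesses grade
geometrically (factor 1.15) toward the surface, so elements pack
tightly near the substrate in the contact region.  The one element at
the apex-axis corner legitimately collapses toward a triangle; mesh
validity is therefore checked at the 2x2 Gauss points, where the FEM
evaluates Jacobians.  If a local fold appears (the free surface can hug
the substrate at distances far below the element size), a few Laplacian
sweeps on interior nodes untangle it deterministically.

**Flow solve.**  Equal-order bilinear velocity/pressure elements with
the axisymmetric weight `r`, stabilised by perturbing incompressibility
to `div(v - eps grad p) = 0` with `eps = h_mesh^2/(2 mu)`.  The
velocity solve (traction on the free surface, no-slip on the disc,
`v_r = 0` on the axis) alternates with the pressure update
`(1/mu)(p_new - p_est) = -div v + div(eps grad p_new)` until the
relative pressure change drops below 1e-6; both subproblems are SPD and
factorised once per time step, and the pressure is warm-started from
the previous step.  The update sign is chosen so the alternation is a
contraction (a Fourier mode analysis of the divergence-form
discretisation shows the opposite sign amplifies smooth pressure
modes); the fixed point — the perturbed continuity equation — is
unaffected.  Convergence takes 10-25 iterations in practice.

A note on measuring incompressibility: at the fixed point the discrete
weak divergence equals `-eps Kp p` exactly, so divergence residuals
against smooth test fields scale linearly with `eps`
(`divergence_residual()`).  The pointwise L2 divergence does not reach
zero on a fixed mesh, because lowering `eps` also weakens the pressure
stabilisation and admits small-scale pressure modes; this is inherent
to the equal-order pair, not a solver defect.

**Time stepping.**  Forward-Euler boundary advection with the step
chosen so fluid moves at most 10% of any element (per-element size over
local speed), capped at 0.5 s in quiescent phases; a step that would
self-intersect the contour is rejected and retried with half the step
(at most 5 times).  Continuum contact capture, discrete ring capture,
smoothing, resampling and volume correction follow in that order.

## What the synthetic world does and does not establish

All tests run on configurations generated in code: analytic spheres and
caps for geometry, a manufactured axisymmetric Stokes solution (a point
force's far field on an off-axis patch) for the FEM, logistic and
power-law curves (optionally with multiplicative noise) for the
analysis layer, and the scaled-down simulation suite (coarse meshes of
about 350-600 elements, horizons of 130-400 s) for the physics
criteria.  A green suite establishes internal consistency — equilibrium
agreement with the wetting relation, the 1/2 power law, sigmoidal
active spreading at about 3 um^2/s, density-limited discrete spreading
— at coarse resolution.  It does not establish quantitative agreement
with any particular experiment beyond the printed anchors, nor
mesh-converged values of the figure-level curves: the resolution
studies (Courant halving, element doubling) bound the discretisation
drift at about 2% on short horizons only.

Known limitations: the discrete variant approaches the continuum
trajectory at high site density through the rising phase but plateaus
earlier, because its capture distance (tension-suppressed membrane
fluctuations) keeps shrinking while the continuum capture height stays
at the potential standoff; two-member lattice ensembles are too small
to resolve how ensemble spread shrinks with density; and bond rupture,
receptor depletion and non-axisymmetric shapes are out of scope.

## Parameter summary

| parameter | default | units | meaning |
|---|---|---|---|
| `mu` | 200 / 1660 | Pa s | cytoplasmic viscosity (passive / active) |
| `cell_diameter` | 8.5 | um | resting diameter |
| `tau_a`, `k1` | 0.01, 0.16 | mN/m | tension law below the knee |
| `tau_b`, `k2` | 0.0516, 0.545 | mN/m | tension law above the knee |
| `ratio_trans` | 1.26 | — | area ratio at the knee |
| `sigma_prot_max` | 3500 | Pa | protrusion stress ceiling |
| `s0` | 0.8 (0.4-2 tested) | um | protrusion decay length |
| `t0` | 66 | s | protrusion decay time (discrete) |
| `D0` | 0.05 | um | adhesion potential range |
| `W_adh` | 1846.77 | Pa | adhesion scale at 100% density |
| `temperature` | 310 | K | thermal energy scale |
| `kappa_b` | 2e-20 | J | membrane bending modulus |
| `K_d` | 1e-6 | M | receptor-ligand dissociation constant |

## Reproducing the headline checks

```{r example}
library(phagospread)

## Brownian zipper at 30% relative density: power law and equilibrium
ser <- run_simulation(run_config("brownian", rho_rel = 30, t_end = 400,
                                 n_free = 50, layers = 8))
loglog_slope(ser)              # exponent ~ 0.5
equilibrium_check_brownian(ser)  # plateau vs Young-Dupre, cap fit

## protrusion-only spreading: sigmoid at ~3 um^2/s
ser2 <- run_simulation(run_config("protrusive_continuum", rho_rel = 0,
                                  t_end = 200, n_free = 50, layers = 8))
sigmoid_fit(ser2)

## discrete adhesion: density-limited spreading
ens <- run_discrete_ensemble(
  run_config("protrusive_discrete", rho_l = 300, t_end = 130,
             n_free = 44, layers = 8), n_shifts = 2)
max(ens$mean$A_c)
```
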