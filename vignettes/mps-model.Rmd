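---
title: "Coarse-grained Langevin dynamics of a magnetic polymersome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained Langevin dynamics of a magnetic polymersome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The system and the model

A magnetic polymersome (MPS) is a hollow diblock-copolymer vesicle whose
membrane confines mobile magnetic nanoparticles (MNPs) between its two
polar interfaces. The particles, typically ~10 nm maghemite, are free to
move inside the thin hydrophobic layer, interact through dipole--dipole
forces, and respond to an applied field; the chains they form push against
the membrane and deform the whole vesicle.

`mpsdyn` models the membrane as **two concentric triangulated shells**. Each
shell is a quasi-uniform Fibonacci-lattice mesh on a sphere, triangulated
by its convex hull; every node is a coarse-grained "blob" with a finite
soft-sphere diameter. Three elastic couplings act on a shell pair:

* **neo-Hookean edge springs** on every mesh edge: the scalar force
  `ks * [(x^0.5 + x^-2.5)/(x + x^-3)] * (r - r0)/r0` with `x = r/r0`,
  stiffening under large strain;
* a **local area constraint** on every triangle: each vertex feels
  `-kal (S - S0)/S` along the unit vector from the triangle centroid to
  that vertex;
* **harmonic tethers** between corresponding nodes of the two shells,
  `kh (r - r0)`, holding the inter-shell distance near its built value.

Bending rigidity, global-area and volume conservation are deliberately
absent: the membrane is tensionless and fully solvent-permeable, and only
the above local couplings plus excluded volume give it integrity.

Excluded volume is the **Weeks--Chandler--Andersen** (truncated-shifted
Lennard-Jones) potential with cutoff equal to half the sum of the two
diameters and `sigma = Rcut / 2^(1/6)`; the shift `cshift = eps` makes the
energy fall continuously to zero at the cutoff. The blob diameters
(`dout = 3.1`, `din = 2`) deliberately exceed the mesh edge lengths, so the
blob layers tile each surface and the membrane is impermeable to the
particles. Soft-sphere repulsion acts between **all element pairs except
directly bonded ones** (mesh edges, tethers) and except blob pairs that
already overlap in the as-built reference geometry. These rest-state
exclusions make the constructed vesicle exactly stress-free, which matters:
without blob--blob repulsion the tensionless network crumples thermally,
and without the rest-state exclusions the shells inflate away from their
reference radii and squeeze the particle layer.

Each nanoparticle carries a permanent reduced moment along the unit vector
`e_i`. The magnetic energy per particle (in kT units) is

```
U_i = -xi (e_i . h)  +  lambda a^3 sum_j [ (e_i.e_j) - 3 (e_i.rhat)(e_j.rhat) ] / r^3
```

with `lambda` the dipolar coupling (contact dipole--dipole energy over kT)
and `xi` the Zeeman coupling (Langevin argument). Dipole sums are direct
all-pairs in a single box — there are at most 393 particles and no periodic
images, so no Ewald machinery is warranted.

## Dynamics

All elements follow the inertial Langevin equation
`m r'' = F - zeta r' + f(t)` with white noise obeying the
fluctuation--dissipation relation `<f f'> = 2 zeta kT delta`. Friction is
Stokes-like: each element's `zeta` scales with its soft-sphere diameter.
Because the particles are rotationally free, the package adds the
rotational analogue — without it the dipoles could never align with the
field: angular velocities obey `I w' = tau - zeta_r w + tau(t)` with
`tau = e x (xi h + b_dip)` the rigid-dipole torque conjugate to the
orientation energy, and `zeta_r/zeta_t = a^2/3` by default (the Stokes
ratio for a sphere).

Integration uses the BAOAB splitting of stochastic velocity Verlet. Its
configurational sampling error is O(dt^2) and, with the defaults
`dt = 0.005`, `m = 1`, `zeta_t = 1`, completely negligible against the
statistical noise: the test suite verifies equipartition to 1.00 +/- 0.05,
harmonic-well variance to kT/k within 3%, the Einstein relation
`D = kT/zeta` within 5%, and a single dipole's mean alignment at `xi = 5`
against the Langevin function within 3%. With `I = 1` free rotation is
underdamped; this changes orientation *kinetics* but not any equilibrium
average (the Langevin-function check passes exactly because equilibrium
sampling is independent of inertia). The free-rotational-diffusion decay
rate `2 kT / zeta_r` is therefore verified in an overdamped configuration
(`zeta_r = 3`, `I = 0.1`).

Thermostat noise comes from a xoshiro256++ stream seeded from R's RNG and
carried inside the state object, so a `set.seed()` makes whole trajectories
bitwise reproducible, consecutive runs continue the same stream
(`run(a)` then `run(b)` equals `run(a+b)`), and checkpoints resume
identically.

## Geometry, units and loading

Reduced units: lengths in a unit chosen so the particle diameter is
`a = 1.2` (8.3 nm for a 10 nm particle), energies in kT. The reference
geometry is `Dout = 24`, `Din = 16`, `dout = 3.1`, `din = 2`, giving a
particle-accessible layer of thickness
`l = (Dout - dout - Din - din)/2 = 1.45` — just over one particle diameter,
so the particles form a spherical monolayer (quasi-2D diffusion). In
physical terms the vesicle is ~200 nm across with a ~33 nm membrane.

The particle count for a volume fraction `phi` refers to the layer volume
between the blob surfaces: `N = round(phi V_layer / v_p)`; the studied
loadings `phi = 5.5%` and `11%` give 105 and 210 particles. A hard cap of
393 particles reflects the mesh-template capacity. Placement is random
sequential insertion, uniform in direction and admissible radius, rejecting
particle--particle contacts below `a` and particle--blob contacts below the
WCA cutoff.

The material-parameter mapping uses the SI point-dipole contact energy
`mu0 mu^2 / (4 pi a^3)` for `lambda`. The factor `1/(4 pi)` is a
documented convention choice: it is the convention under which 10 nm
maghemite (`Ms = 400 kA/m`, room temperature) gives `lambda ~= 1`, the
reference value the rest of the parameter map is anchored to. Note that
`lambda` scales as `Ms^2` — substituting iron (`Ms ~ 2000 kA/m`) raises it
25-fold.

## Preparation protocol

1. **Thermalisation** (stage A): all couplings except the magnetic ones.
2. **Ground state** (stage B): dipolar interactions on at `H = 0`; the run
   continues in windows until the trailing-window mean total energy changes
   by less than a relative tolerance (default `1e-3` over 10^4-step
   windows), or a window budget is reached (then flagged, not fatal —
   strong-coupling chain coarsening is slow and the flag is part of the
   result).
3. **Quasi-static magnetisation**: the field is raised along a
   non-decreasing `xi` schedule (default `0, 0.5, 1, 2, 3, 5, 7, 10`),
   equilibrating then measuring at each level. The ramp is not a
   convenience: quenching straight to `xi = 10` traps the strongly coupled
   system in flux-closure rings with low magnetization, whereas the ramp
   reproducibly yields field-aligned chains and elongation.

Field-sweep curves can be averaged over independent realisations
(`magnetisation_curve()`, default 10), matching how such sweeps are
normally reported.

## Calibrated elastic constants

The elastic constants are not dictated by the model, only that they be
"relatively small" so the vesicle stays soft. They were calibrated once,
against two physical requirements, and then frozen:

* **Impermeability.** With `ks = kal ~ 1` (and up to ~5 at `eps = 1`) the
  membrane is so floppy that thermal edge fluctuations transiently open
  pores wider than the particle--blob cutoff and particles leak out within
  10^4--10^5 steps — violating the model premise that the boundaries are
  impermeable. The defaults `ks = kal = 10`, `kh = 5`, `eps = 2` keep every
  particle confined over multi-10^5-step strong-coupling runs.
* **Deformability.** The same defaults leave the vesicle soft enough that
  at `lambda = 5`, `phi = 11%` the quasi-static sweep raises the aspect
  ratio from ~1.04 to ~1.10--1.12 by `xi = 10`, with magnetization >0.9 —
  chain-driven elongation, not rigid-body artefact.

All four constants remain user-visible knobs in `forcefield_params()`.

Mesh resolution interacts with impermeability: at 162 nodes per shell the
blob spacing (edges ~3.6) exceeds the particle--blob cutoff (2.15) and the
membrane leaks regardless of stiffness, so all vesicle-scale runs — tests
included — use the full 393-node shells. They cost little: the dipole
all-pairs sum dominates the step, not the mesh.

## Observables

* **MSD** over all particles and all time origins; the log--log slope over
  a lag window distinguishes free (`~1`) from chain-hindered (`<1`)
  diffusion. In the spherical monolayer the motion is quasi-2D and the MSD
  saturates at lags comparable to the vesicle circumference; exponent
  windows should stay below that scale.
* **Aspect ratio**: primary estimator `sqrt(v_par / gm(v_perp))` from the
  outer-shell node covariance (exact for affine stretches, rotation- and
  scale-invariant); a slab cross-section estimator (`delta = 1.0`) serves
  as a fidelity cross-check.
* **Cluster statistics**: single-linkage with the dipolar-fluid bond
  criterion `r < 1.3 a`; reports size histogram, largest cluster, bonded
  fraction.
* **Magnetization** `<e . h>` and **sigmoid fits** of aspect-ratio sweeps
  with the 4-parameter logistic
  `ar0 + (ar_inf - ar0)/(1 + exp(-(xi - xi_half)/width))`.

## Numerical choices and degenerate inputs

* The neo-Hookean *energy* has no closed form; where an energy is needed
  (breakdown reporting, gradient cross-checks) it is integrated from the
  printed force law by 16-point Gauss--Legendre quadrature, accurate to
  machine precision over the strains that occur.
* The local-area constraint force is implemented exactly as defined —
  magnitude `-kal (S - S0)/S` along unit centroid-to-vertex vectors. This
  force is *not* the gradient of a potential, and on scalene triangles the
  three vertex forces do not cancel exactly, so it injects a small net
  force (~10^-2 reduced units on a thermalised shell, against thermal
  forces ~20). The thermostat friction absorbs it; the quadratic
  `0.5 kal (S-S0)^2/S0` in the energy breakdown is bookkeeping only.
  Momentum-conservation checks therefore apply to the pairwise terms.
* Zero-length edges, zero-area triangles, coincident particles and empty
  ensembles raise immediate errors rather than propagating NaNs; the
  integrator aborts on non-finite state with the step index.
* Sigmoid fits of flat data return a degenerate-width flag instead of a
  spurious parameter set.

## Desk-scale problem sizes

The test suite runs the full 393-node geometry with 210 particles
(`phi = 11%`). Ground states use 2x10^4 pre-thermalisation steps plus up to
9x10^4 windowed equilibration steps and a 2x10^4-step sampled production
segment; field sweeps use a 5-level ramp (`0, 1, 3, 5, 10`) with 8x10^3
equilibration and 6x10^3 measurement steps per level, one realisation per
condition. These sizes resolve the qualitative contrasts (chain formation,
hindered diffusion, field-induced elongation, loading dependence) as clear
inequalities; fully converged sweep *magnitudes* (e.g. the saturation
aspect ratio near 1.17 at the strongest coupling and loading) require the
full protocol — longer level equilibration and ~10-realisation averaging —
which is hours of CPU, via `magnetisation_curve()`.

## What the generator does and does not emulate

The builder generates the study conditions themselves (geometry, loading,
coupling constants), not a surrogate of real data: every simulation input
is synthetic by construction. What the model does *not* represent: a real
MPS has polydisperse particles, a viscoelastic (non-Newtonian)
intra-membrane fluid, hydrodynamic interactions, bending rigidity and
thermal area fluctuations of real polymer interfaces, and magnetic
anisotropy axes within the particles. Passing tests therefore validate the
coarse-grained model's internal physics, not quantitative agreement with
any specific experimental vesicle.

## Known limitations

* Quantitative kinetics (absolute MSD scales per step) depend on `dt`,
  `m`, `zeta` — the model's time unit is not mapped to seconds, so only
  shapes and exponents are meaningful in time.
* The aspect-ratio response at desk scale is noisy at weak coupling;
  single-realisation sweeps at `lambda = 1` do not resolve a smooth curve
  (more realisations are needed, as for any stochastic sweep).
* The Fibonacci mesh is quasi-uniform (edge-length ratio < 2), not the
  perfectly regular triangulation an icosahedral subdivision would give at
  magic node counts; its largest triangles set the leak-tightness margin
  discussed above.
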