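---
title: "The biofilmsim individual-based model: processes, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The biofilmsim individual-based model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmsim)
```

## The model in one page

`biofilmsim` is an individual-based model (IbM) of microbial communities at
the micro-scale, built for biofilms. Every microbe is an explicit soft
sphere with its own position, velocity, mass, diameter, and — for
EPS-producing heterotrophs — an extracellular-polymer shell tracked as
outer mass and outer diameter. Microbes belong to functional groups
(heterotrophs HET, ammonia oxidisers AOB, nitrite oxidisers NOB, inert EPS
and DEAD types, or any user-defined group) that share kinetic and
mechanical parameters.

The computational domain is a rectangular box, periodic on its four side
faces, with an impermeable substratum at the bottom and the well-mixed bulk
liquid above. Chemistry lives on a uniform cubic voxel grid; mechanics and
biology live on the particles. Three processes run on three timescales:

* **Biology** (minutes–hours): growth `dm/dt = mu m`, instantaneous
  division, death, removal, EPS excretion, lysis of dead biomass.
* **Chemistry** (~1e-4 s steps): diffusion–advection–reaction of every
  solute, driven to pseudo-steady state within each biological step; a
  chemostat mass balance moves the bulk concentrations; optionally
  per-voxel pH by charge balance and gas–liquid transfer.
* **Mechanics** (~1e-7 s steps): soft-sphere DEM — Hookean contact with
  viscoelastic damping, van der Waals EPS adhesion, drag against a
  prescribed fluid velocity field — integrated by velocity Verlet until the
  community's virial pressure stabilises.

The coupling is the frozen-state (pseudo-steady-state) approximation: the
converged solute field is held constant while biology advances one step,
and biology is frozen while mechanics relaxes. This is what makes the
three-timescale problem tractable.

## Growth kinetics

Two growth laws are implemented.

**Monod-based.** Each functional group carries one or more pathways;
pathway `p` contributes

    mu_p = mumax * eta_p * prod_s S_s / (K_{p,s} + S_s)

over its limiting solutes, with `eta = 1` for aerobic growth and
`eta = etaHET < 1` for heterotrophic growth under anoxic denitrifying
conditions. The net rate is the pathway sum minus a first-order decay rate
`b`. Reaction rates per voxel follow the stoichiometric coefficients of
each pathway applied to `mu_p * m_i / V_voxel`, summed over the microbes in
the voxel; consumption is negative, production positive. Zero
concentrations need no floor: the Monod factor is simply zero.

**Energy-based.** Growth is limited by harvested energy:
`mu = Y (q_met - m_req)`, with `q_met` saturating (Monod form) on the
*non-charged* form of the substrate as delivered by the pH speciation, and
`m_req` the maintenance requirement; a microbe below maintenance shrinks.
The per-species reaction rate is `R = mu (Cat / Y + Ana) X` distributed by
the overall-reaction stoichiometry. The yields `Y`, catabolic and anabolic
energies `Cat`, `Ana` are configuration inputs (they would come from an
energy-dissipation calculation done offline); the package does not estimate
them. The Monod-based model runs without pH and gas coupling; the
energy-based model enables both.

The shipped nitrifying parameter set uses standard activated-sludge-style
values: HET `mumax` 6 d^-1, yield 0.61, EPS yield 0.18, `etaHET` 0.6,
decay 0.4 d^-1; AOB `mumax` 1 d^-1, yield 0.33; NOB `mumax` 0.79 d^-1,
yield 0.083; biomass density 150 kg m^-3, EPS density 30 kg m^-3; division
at 1.3 um, death below 0.4 um. All of them are plain configuration values —
the engine is parameter-agnostic.

## Biological events

* **Division** triggers when the *core* diameter reaches the group
  threshold (biomass, not the EPS shell, drives division). The parent mass
  is split exactly: daughter 1 keeps the parent position and a fraction
  `f ~ U(0.4, 0.6)` of mass; daughter 2 is placed along a uniform random
  direction. The default centre separation is the daughters' radius sum
  (touching spheres); the alternative `diameter_sum` placement is available
  as a configuration switch. A placement below the substratum is reflected.
  We chose touching placement as the default because a diameter-sum gap
  leaves an unphysical void that mechanics must immediately close.
* **Death** uses a strict `<` on the core diameter. Dead cells switch to
  the DEAD group: they keep their mechanics (they still occupy space) but
  do no biology. Their biomass converts linearly (first-order rate) to
  soluble substrate — lysis — and once the diameter falls below a tenth of
  the death threshold the agent is removed.
* **EPS excretion**: when the shell ratio (outer/core diameter) of a
  heterotroph exceeds its threshold, a fraction `g ~ U(0.4, 0.6)` of the
  shell mass leaves as a free EPS particle placed in contact with the
  parent. EPS mass is conserved exactly at the event.

All stochastic choices (division fraction and direction, excretion fraction
and direction, inoculum placement) draw from R's global RNG, seeded once
per run, which is what makes seeded runs bit-reproducible and restartable.

## Solute transport and the bulk liquid

The transport equation `dS/dt = div(D grad S) - div(v S) + R` is
discretised on voxel centres with the 7-point Laplacian and
central-difference advection, advanced by forward Euler (FTCS). The
timestep default is 0.9x the stability bound `dx^2 / (6 D)`; a violated
bound or an advective CFL above 1 is an error, not a warning. Boundary
conditions follow the standard biofilm setup: Dirichlet bulk value at the
top face (ghost value `2 S_b - S`), zero-flux Neumann at the substratum,
periodic sides. Voxels labelled bulk are clamped to `S_b` every step —
the bulk is perfectly mixed by assumption.

Central-difference advection is kept for fidelity to the discretisation
choice stated for the model; it is second-order but not monotone, so
high-Peclet velocity fields need grid refinement (no upwinding is applied).

Steady state is declared when the largest relative per-sweep change falls
below `tol` (default 1e-6; the miniature scenario uses 1e-5). The reaction
term is re-evaluated each sweep against the frozen community: per-voxel
biomass is aggregated once per biological step, only the concentration
factors change between sweeps.

The bulk liquid follows the chemostat balance
`dS_b/dt = (Q/V)(S_in - S_b) + A_f/(V Lx Ly) * Int R dV`, forward-Euler
over the biological step, floored at zero; solutes flagged `fixed_bulk`
(aerated oxygen) are skipped.

Region labelling is dynamic: the biofilm region reaches the top of the
highest particle *including its EPS shell* (the biofilm is the volume
occupied by microbes and their EPS); the boundary layer extends a
configured height above it; interfaces snap up to whole voxel faces so
regions conform to the grid. Using top-of-sphere rather than centre height
for the thickness is a choice — it is consistent with the height map used
by the morphology statistics, and it is configurable in the sense that the
labelling derives from one function (`biofilm_thickness`).

## pH and gas-liquid transfer

Acid-base systems are treated as equilibria. Each dissociating nutrient is
a ladder of forms with known charges and successive equilibrium constants,
so every form's concentration is a closed-form function of `[H+]`. The
proton concentration solves the charge balance

    [H+] + sum m [S^m+] = [OH-] + sum n [S^n-]

by Newton–Raphson on `log[H+]` with a maintained bisection bracket in
`[1e-14, 1]` mol/L; the charge imbalance is monotone in `[H+]` for valid
inputs, so the bracket always closes. The accepted root has residual below
`1e-12 * max(1, total concentration)`. Transport works in kg m^-3; the pH
solver works in mol/L via per-solute molar masses. Equilibrium constants
are taken as supplied at the configured temperature; no temperature
correction is applied to them.

Gas–liquid exchange uses two-film transfer
`R_GL = KLa (S_gas - S_liq / K_H)` into the liquid reaction term and the
matching head-space rate `R_LG = -R_GL V_gas / (Rg T)`, with the head
space sized like the computational domain.

## Mechanics

Forces on particle i:

* **Contact** (core spheres): `F = Kn delta n_ij - m_ij gamma_n v_ij` on
  overlap `delta`, with effective mass `m_ij`. Newton's third law is exact
  by construction.
* **EPS adhesion** (outer spheres, EPS-bearing pairs only — HET–HET,
  HET–EPS, EPS–EPS): `F = Ha r_ij / (12 h_min^2)` attractive, with
  effective outer radius `r_ij`, separation floored at `h_floor`
  (default 1 nm) to regularise the `1/h^2` singularity, and a range cutoff
  of 1.5x the outer radius sum. Groups without shells feel contact only.
* **Drag** against a prescribed, static fluid velocity field:
  `F = -(V_p eps_s beta / eps_f)(u_p - U_f)` with the Stokes-form
  correction `beta = 18 mu_f eps_f / d_p^2`. A particle slower than the
  fluid is pushed along the flow. An over-packed voxel
  (`eps_s >= 1`) is an error.
* **Substratum wall**: Hookean repulsion mirroring the contact law.

Rotation is omitted: no torque model is defined for these forces, so only
translations are integrated (velocity Verlet). Particles wrap across
periodic faces; at the fixed top face they reflect or are removed,
per configuration.

Relaxation runs damped dynamics until the average (virial) pressure

    P = (1/3V) (sum m_i v_i.v_i + sum_{i<j} r_ij . F_ij)

changes by less than `pressure_tol` (default 1e-3) over a 100-step window,
with `V` the summed outer-sphere volume. Pair damping alone cannot remove
centre-of-mass motion, so relaxation adds a background viscous force with a
near-critical per-particle coefficient `sqrt(Kn m)` by default (set
`viscous = 0` to disable). Velocities are zeroed on exit: relaxation seeks
the static packing, not a dynamical state. A relaxation that exhausts its
step budget returns the state with a warning — the next biological step
continues from there, which bounds the mechanical work per step the same
way the multi-timescale loop intends.

## Observables

The height map bins the substratum plane (default bin = voxel size) and
records the top of the highest particle per bin, shell included. Mean
height and roughness are the discrete surface integrals — roughness is the
population standard deviation of bin heights. Area density is total mass
(core + shell) per substratum area; whether EPS mass belongs in it is not
settled usage, so including it is a documented choice. Floc statistics:
equivalent diameter of the volume-matched sphere, and a box-counting
fractal dimension over dyadic grids anchored at the bounding cube (at
least 4 scales, least-squares slope of `log N` vs `log 1/l`); a single
particle has no dimension and reports `NA`.

## The driver, determinism and restart

Per biological step the driver executes: velocity/drag inputs, solute
steady state, bulk update, growth, division/death/EPS/lysis, mechanical
relaxation, region and bookkeeping updates. Stages are enabled by the
`processes` list in the configuration; disabling one skips exactly that
stage. Each stage failure is reported with the stage name and step index.

Determinism is a contract: one seeded global RNG, no hidden state, so a
fixed seed reproduces the trajectory bit for bit, and a restart (particles,
fields, bulk, clock, RNG state, version tag) continues a run step-for-step
identically to the uninterrupted one.

Output formats are plain-text particle tables, VTK legacy ASCII (polydata
for particles, structured points for fields) readable by ParaView, CSV
time series of the observables, and the binary restart file.

## The miniature nitrifying-community scenario

`make_scenario("nitrifying_community")` is the package's integration
scenario: 40 cells (20 HET, 10 AOB, 10 NOB) inoculated on the substratum of
a 100 x 100 x 100 um domain with a 10 um grid, five solutes (organic
substrate, O2, NH4+, NO2-, NO3-), aerated O2 held at 1e-2 kg m^-3, high
influent NH4+ (0.03 kg m^-3), no N oxides in the influent, biological step
0.25 h, 72 steps (18 h).

The regime it emulates — heterotrophs outgrow nitrifiers while substrate
is plentiful, then the system turns substrate-limited for HET while
abundant NH4+ keeps nitrifiers growing — develops over ~160 h in a full
simulation. An 18 h desk-scale miniature must reach that regime inside its
window, so the chemostat coupling is scaled accordingly: influent substrate
sits at the HET half-saturation level (4e-3 kg m^-3) and the biofilm area
per reactor volume is large (A_f/V = 3e4 m^-1, i.e. many replicates of
this micro-domain per reactor volume). These are scenario parameters, not
model changes; with a slower reactor the same dynamics simply take longer.
Heterotrophic denitrification pathways carry an oxygen inhibition factor
`K_I,O2 / (K_I,O2 + S_O2)`, the standard way anoxic growth is switched off
in oxygenated regions.

What the miniature shows: the mechanistic coupling between growth,
consumption, the bulk balance and community composition. What it does not
show: hydrodynamic detachment (no CFD), thick-film diffusion limitation
(the 18 h film is sparse), or quantitative agreement with any particular
reactor — its assertions are trends, not numbers.

## Known limitations

* No computational fluid dynamics: the velocity field is prescribed, not
  solved; momentum feedback from particles to fluid is out of scope.
* Decay is a biomass sink only; endogenous-respiration stoichiometry
  (O2 use by decay) is not routed to the solute fields.
* Central-difference advection needs fine grids at high Peclet number.
* Rod shapes, motility and per-cell genomes are out of scope.
* The energy model's speciation is evaluated per voxel per sweep; it is
  intended for coarse grids (the per-voxel charge balance is exact but not
  vectorised across voxels).

## Problem sizes used by the test-suite

The suite runs entirely from generated data: oracle problems use 1D
columns of 32–64 voxels and two-body or few-hundred-body mechanical
systems; property checks loop over a few thousand seeded events; the
miniature scenario is the 60-step run described above. These sizes were
chosen so every closed-form comparison sits well inside its asymptotic
regime while the whole suite stays fast to iterate on.
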