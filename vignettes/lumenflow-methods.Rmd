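---
title: "Motility-driven luminal transport: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motility-driven luminal transport: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

lumenflow simulates how the two canonical motility programmes of the human
small intestine — fed-state **segmentation** (standing, rhythmic
circumferential contractions) and fasted-state **peristalsis** (a
propagating contraction wave) — move dissolved therapeutics from a released
bolus to the epithelial surface. The model system is a macromolecule
(insulin, 2 mM) co-released with a permeation enhancer (sodium caprate,
C10, 100 mM) into a fluid-filled lumen segment, with delivery read out as
near-wall accumulation, wall surface concentration, and a colocalisation
score for the pair.

## Wall kinematics

The lumen is an axisymmetric tube of rest radius $r_0$ whose wall deforms
with prescribed kinematics; the fluid responds passively (no
fluid–structure coupling). For segmentation the radial wall velocity is

$$U_r(z,t) = \frac{2\pi\delta}{t_p}\cos\!\frac{2\pi z}{\lambda}
            \cos\!\frac{2\pi t}{t_p} + f(t),$$

a standing wave of amplitude $\delta$, wavelength $\lambda$ and period
$t_p$, plus a spatially uniform correction $f(t)$ chosen so the wall motion
neither ejects nor ingests fluid. Writing the wall position as
$h(z,t) = r_0 + \delta\sin(2\pi t/t_p)\cos(2\pi z/\lambda) + B(t)$ and
imposing $\int_0^\lambda h^2\,dz = r_0^2\lambda$ at every instant gives the
closed form

$$B(t) = \sqrt{r_0^2 - \tfrac{\delta^2}{2}\sin^2(2\pi t/t_p)} - r_0,
  \qquad f = B'(t),$$

which makes volume conservation an *identity*, not a numerical property:
the package's `check_volume_conservation()` evaluates the quadrature error
of the identity (round-off, $<10^{-10}$ relative). The radicand is positive
iff $\delta < r_0\sqrt2$, which bounds the admissible amplitudes.
Peristalsis is the pure travelling wave
$h = r_0 + \delta\sin(2\pi(z - ct)/\lambda)$.

Geometry derives from three clinically reported quantities: the pocket
volume $V$ (a rest cylinder of one wavelength holds it,
$r_0 = \sqrt{V/\pi\lambda}$; 2 mL pairs with $\lambda$ = 2.4 cm and 10 mL
with 4.1 cm), the occlusion ratio OR (minimum-to-rest radius of the
contracting lumen), and the intensity (light 7 s / 0.5 cm s$^{-1}$,
moderate 5 s / 1 cm s$^{-1}$, vigorous 3 s / 1.5 cm s$^{-1}$ for
period/wave speed). Because the minimum realised segmentation radius
includes the offset $B(t)$, inverting OR for $\delta$ gives
$\delta = r_0(-2\,\mathrm{OR} + \sqrt{6 - 2\,\mathrm{OR}^2})/3$; an
`include_offset = FALSE` switch provides the bare-sinusoid inversion
$\delta = (1-\mathrm{OR})r_0$ for comparison. We default to the
offset-aware form because OR is defined on the wall position the epithelium
actually reaches.

## Fluids and species

Luminal contents are either water at 37 °C (Newtonian, 0.6913 mPa s,
0.9933 g cm$^{-3}$) or a nutritional drink modelled as a shear-thinning
power law $\mu = K\dot\gamma^{n-1}$ with the shear rate clamped to
$[10^{-3}, 10^3]$ s$^{-1}$ to regularise the zero-shear singularity. The
shipped drink parameters ($K$ = 6 mPa s$^n$, $n$ = 0.65,
$\rho$ = 1.05 g cm$^{-3}$) are **documented stand-ins**, not fitted
rheometry. The consistency was fixed once by requiring the simulated drink
to reproduce the reported drink-versus-water flow contrasts of the motility
study (+19% peak luminal velocity and a roughly 2.5-fold surface shear
stress). This choice matters physically: consistencies typical of
*undiluted* nutritional supplements (tens of mPa s$^n$) push the baseline
pocket flow to $Re \lesssim 1$, the kinematically reversible Stokes regime
in which periodic wall motion produces no net Lagrangian drift and
essentially no radial drug delivery — contradicting every reported drink
observation. The delivery metrics themselves played no part in the
calibration, and measured parameters can be supplied through
`fluid_model()`. Any drink-dependent velocity comparison should still be
read as directional.

Insulin diffuses at $1.11\times10^{-6}$ cm$^2$ s$^{-1}$ in water at 37 °C.
C10's diffusivity is concentration dependent; we anchor it at 5.50× insulin
at 1 mM and 3.15× at 100 mM and interpolate linearly in $\log_{10}c$
(clamped outside 1–100 mM) — with two anchors this is the smooth monotone
choice. Diffusivities in other fluids follow Stokes–Einstein scaling with a
*single scalar* reference viscosity, evaluated at the contraction shear
scale $(2\pi\delta/t_p)/r_0$; the adjustment is deliberately not
field-coupled, matching how a scalar diffusivity enters the transport
module. We note the printed anchor ratios make the enhancer *more*
diffusive than insulin, and the implementation follows those numbers.

## Flow solver

The solver integrates the incompressible axisymmetric Navier–Stokes
equations on the deforming lumen. The single-valued wall shape admits an
exact boundary-fitted mapping $\eta = r/h(z,t)$, so the moving domain
becomes a fixed rectangle and the mesh velocity enters only the advective
terms (an arbitrary Lagrangian–Eulerian formulation in mapped coordinates —
chosen over remeshing because the mapping is exact and cheap). Cell-centred
finite volumes carry velocity and pressure; radial faces are geometrically
stretched toward the wall.

Time stepping is a semi-implicit projection:

* advection (second-order upwind) and the full consistent viscous operator
  are explicit; a Douglas ADI pass (θ = 1) over the axial and the
  mapped-radial diffusion operators — the radial one carrying the
  $(1 + (\eta h_z)^2)$ metric coefficient that covers the mixed-derivative
  stiffness — stabilises the stiff directions without losing consistency;
* the pressure is incremental and rides through the stages; face volume
  fluxes are assembled by Rhie–Chow momentum interpolation (no
  checkerboarding on the collocated grid) and projected so that every
  cell satisfies $\sum_f F_f + \mathrm{d}V/\mathrm{d}t = 0$ *discretely*,
  with the geometric conservation term evaluated from the discrete volume
  change. The pressure Poisson operator is symmetric positive
  semidefinite; a tiny Tikhonov shift makes it definite and CHOLMOD
  refactors it each step reusing the symbolic analysis.
* the time step honours an advective CFL bound (≤ 0.35) and a
  *splitting-accuracy* bound $\nu\,\Delta t\,(\pi/r_0)^2 \lesssim 0.5$: the
  projection's pressure–viscous splitting is only first-order accurate in
  $\Delta t$ when the viscous relaxation of the smooth radial modes is
  resolved, and letting implicit diffusion take arbitrarily large steps was
  observed to bias steady Stokes-regime solutions.

For variable viscosity the viscous term uses the
$\nabla\!\cdot(\mu\nabla u)$ form without the transpose contribution
$\nabla\mu\cdot(\nabla u)^T$ — exact for Newtonian fluids (all verification
fixtures) and a conventional approximation for generalised Newtonian flow.

Peristalsis is solved in the **wave frame**, where the wall shape is static
and the flow steady: wall material moves with $(-c, -c\,h')$ (no slip, and
exactly tangential, so no penetration), the ends are periodic over one
wavelength and the net pressure rise per wavelength is zero (free pumping).
The laboratory field adds $c$ to the axial component. Pseudo-time marching
declares convergence on the relative velocity change per unit time, with a
minimum integration time covering the slowest physical transient (viscous
relaxation in the Stokes regime; advective turnover plus radial diffusion
at moderate Reynolds number) so the residual test cannot fire prematurely.

## Scalar transport

Transport of the two species is a conservative finite-volume
advection–diffusion update driven by the *projected face fluxes* of the
flow step. Because those fluxes satisfy the discrete geometric conservation
law, a uniform concentration in any incompressible flow stays uniform to
round-off, and closed-domain mass is conserved exactly (the acceptance
suite verifies 0.1 % over full runs, comfortably). Advection is MUSCL
(minmod) upwinding — the motility cases sit at Péclet numbers of $10^5$ and
above, so positivity matters more than formal accuracy; diffusion is
explicit because macromolecular diffusive time steps are orders of
magnitude above advective ones. Axial ends are open for the scalar even
where the flow is periodic (mass escapes with first-order advective
outflow, zero diffusive flux, zero-concentration inflow), mirroring the
physical picture of an open gut segment.

The bolus is an isotropic Gaussian in $(z, r)$ about the centreline,
released instantaneously at $t=0$ with per-species peak $c_i$; both species
share one geometry (co-administration premise). The default width
$\sigma_b = r_0/10$ is a modelling choice — the source study does not state
a bolus geometry — and is exposed as a knob (`sigma_b`); delivery metrics
shift modestly with $\sigma_b$ because near-wall arrival is
convection-controlled. Cells are initialised with *exact* cell averages
(erf integrals axially, annulus integrals radially), so the released moles
match the closed-form Gaussian integral at any resolution, while the
discrete peak approaches $c_i$ as the grid refines. Release positions:
"most occluded" is the pocket centre for segmentation (the wave trough for
peristalsis), "least occluded" a quarter wavelength away on the
centreline. For the 30-pocket peristalsis domain the release pocket sits
near the wave-frame upstream end so the backward-drifting luminal content
stays inside the domain for all 30 periods; the run aborts with an
instructive error if mass nears the downstream end.

## Delivery metrics and colocalisation

Per sampled instant the package reports: the percentage of released moles
within wall-adjacent shells of thickness $D/15$ and $D/30$ (with $D = 2r_0$
the rest diameter — the shells hug the instantaneous wall, mimicking the
villous zone, while the rest diameter keeps their thickness constant); the
percentage escaped from the release pocket (a fixed one-wavelength axial
window; mass leaving the domain counts as escaped); the wall surface
concentration profile $c/c_i$ (quadratic extrapolation with zero normal
slope, consistent with the impermeable wall); its running maximum and the
detection onset ($c/c_i > 10^{-3}$); and wall shear stress (one-sided
quadratic fit of tangential velocity along the wall normal, times the local
apparent viscosity).

Colocalisation of the pair is scored per case as

$$CS = \frac{\bar C_{MM}\bar C_{PE}}
            {1 + \bar{dt}^2 + \bar{dz}^2 + \bar{dr}^2} \in [0,1],$$

where $\bar C$ are each case's time-maximum wall concentrations normalised
by the *ensemble* maximum per species (so at least one case reaches 1), and
the penalties are the absolute separations of the two species' peaks in
time, axial position and radial wall position. The normalisers — total
simulated time $30\,t_p$, wavelength $\lambda$, rest radius $r_0$ — are our
choice (the score's definition leaves them open) and are exposed in
`colocalisation_score()`; $\bar{dr}$ is nearly zero by construction (both
peaks sit on the wall) and is retained for completeness. Whether the
ensemble spans both motility types jointly is likewise configurable; the
default normalises over the full ensemble passed to `colocalise()`.

## Sweep analysis

`run_sweep()` executes a factorial grid over the six variability factors
(motility type, intensity, fluid, pocket volume, OR, release position),
caching per-case summaries and excluding — not aborting on — individual
failures. Downstream:

* `multifactor_compare()` gives per-group medians/quartiles with
  Mann–Whitney (two groups) or Kruskal–Wallis plus pairwise Dunn tests;
  Dunn's z statistics are computed from mean ranks with tie correction and
  Holm adjustment (chosen because the multiplicity rule was left open).
* `cluster_cases()` runs 1-D K-means on CS (default k = 4, many restarts,
  seeded; clusters sorted by mean CS). An exact dynamic-programming 1-D
  clusterer ships as the verification oracle.
* `attribute_factors()` one-hot encodes the categoricals, Min–Max scales
  all features to [0, 1], splits 80/20, grid-searches a gradient-boosted
  tree regression with 3-fold CV over trees 50–700, learning rate
  0.005–0.2, depth 3–9, subsample 0.6–1.0, and reports exact TreeSHAP
  contributions with a mean-|SHAP| ranking (one-hot columns folded back to
  their parent factor). By default it trains on the largest CS cluster
  (the bulk of cases), with `train_on = "all"` as the alternative; both
  modes exist because the choice is a judgement call, not a derivable
  fact. Held-out fit statistics (MSE/RMSE/R²) are reported for the
  specific data and seed at hand; they depend on the split and search path
  and are not comparable across environments.

## Verification strategy

Every solver claim is backed by an oracle that shares no discretisation
code with the production path:

* **Poiseuille**: body-force-driven flow in a rigid tube; parabolic profile
  and $\tau_w = 4\mu U/R$ to < 1 %.
* **Manufactured solution**: a divergence-free field from a Stokes
  streamfunction plus smooth pressure; residual source terms are evaluated
  by high-accuracy finite differences of the closed forms; observed spatial
  order ≈ 2 across grid doublings.
* **Lubrication peristalsis**: the classical long-wavelength analysis
  ($q = -c\pi\langle h^{-2}\rangle/\langle h^{-4}\rangle$ in the wave
  frame, free pumping) by quadrature; the 2-D solver agrees to well within
  5 % at $\lambda/r_0 = 50$, $Re \sim 10^{-3}$.
* **Gaussian diffusion**: axial variance growth $\sigma_b^2 + 2Dt$ to
  < 1 %.
* **Planted-effect sweeps**: `synthetic_sweep_fixture()` generates
  factorial tables with known additive effects and noise; the attribution
  pipeline must rank the planted dominant factor first across repeated
  seeds.

The synthetic sweep emulates the *shape* of real sweep output (factor
levels, bounded CS, noise); it does not emulate CFD nonlinearities, so a
passing attribution test certifies the pipeline, not the physics upstream
of it.

## Problem sizes and what the defaults show

The default `"coarse"` resolution solves the flow at 20 radial × 32 axial
cells per wavelength (wall-stretched), exploiting the $\lambda$-periodicity
of the segmentation kinematics to compute the flow on a single wavelength
and tile the projected fluxes across the 3-pocket transport domain. The
transport grid is finer — 80 radial × 128 axial cells per wavelength — 
because the near-wall delivery rides on phase-coherent advection that
coarse-grid numerical diffusion destroys: a diffusion-free Lagrangian
particle oracle shows the material migration the Eulerian field must
reproduce, and the near-wall percentages converge to it only once the
transport grid reaches this resolution (the streamfunction-interpolated
flux refinement keeps the finer grid exactly conservative). This setting
runs a full 30-period case in a few minutes and is the package's
reproduction default. The `"production"` preset (64 × 128 flow, 128 × 256
transport per wavelength, first wall cell below $r_0/200$) mirrors a
grid-converged setting for quantitative work; the manufactured-solution
fixture documents how errors contract with refinement. Numbers that depend on the full 72-case factorial at
production resolution (ensemble shear medians, whole-ensemble concentration
ratios) are multi-hour computations; the package exposes them through
`run_sweep()` but the shipped tests check the cheap analytic or
single-case counterparts instead.

## Known limitations

Prescribed wall motion (no fluid–structure interaction), perfectly periodic
waveforms, zero epithelial absorption (by design — isolating hydrodynamic
delivery), no mucus or villous microstructure, scalar Stokes–Einstein
adjustment, stand-in drink rheology, and the Laplacian-form viscous term
for power-law fluids. Each limits what the delivery metrics say about real
intestinal absorption: they rank motility scenarios by hydrodynamic
delivery potential rather than predict absorbed dose.

One numerical limitation deserves emphasis because it decides which
reported quantities are reproducible at reduced resolution. The *wall
surface concentration* is controlled by diffusion across the final standoff
between the advected filaments and the epithelium. Physically that standoff
contracts to the Batchelor scale $\sqrt{D/\dot\gamma}$ — a few micrometres
for these species — at which both species' wall values saturate and differ
only modestly; numerically the standoff stalls at the wall-cell size
(10–30 µm at tractable grids), and the $\mathrm{erfc}$ dependence of
boundary-layer filling then suppresses the slower-diffusing macromolecule
by orders of magnitude relative to the enhancer. Quantities integrated over
finite layers (the D/15 and D/30 mole percentages), escape fractions,
velocities and shear are insensitive to this standoff and converge well;
*ratios between species' wall peaks*, and comparisons of such peaks across
motility types, are not grid-converged at the shipped resolutions and the
corresponding reproduction checks fail honestly. The peristaltic
first-period near-wall squeeze (the >90% D/30 capture) is resolution-aware
in the opposite direction: it converges upward (86.5 → 90.8 → 93.6% across
a doubling ladder of transport grids), so the test evaluates it at the
preset transport resolution over the first periods while long peristalsis
runs keep a lighter transport grid.
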