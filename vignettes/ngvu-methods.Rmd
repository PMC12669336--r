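---
title: "Models and numerical methods in ngvu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in ngvu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ngvu` simulates blood supply and cell-level signalling in a
neuro-glial-vascular unit (NGVU): the functional ensemble of neurons,
astrocytes, vascular smooth-muscle cells (SMC), endothelial cells (EC) and
the vessel they regulate. The package couples four scales:

1. **1D macrocirculation** — pulsatile blood flow on a 37-vessel arterial
   network (aorta to the circle of Willis, with two brainstem branches)
   with 0D Windkessel outlets.
2. **Mesoscale surrogate tree** — a symmetric Murray-law bifurcation tree
   converting the beat-averaged outlet flow of the feeding artery into
   capillary inlet flows.
3. **3D-1D microcirculation** — a stationary pressure/transport problem on
   a capillary centre-line graph embedded in a tissue box.
4. **0D cellular chain** — a quadripartite synapse (Glu and GABA neurons +
   astrocyte + vessel wall) and a neurovascular-coupling cascade ending in
   a dynamic vessel radius, which feeds back on the microcirculation.

## 1D macrocirculation

Each vessel carries cross-section `A(z,t)` and flow `Q(z,t)` obeying mass
conservation and a momentum balance with the friction term
`-2(gamma_bar+2) mu(2R)/rho * Q/A` (profile shape `gamma_bar = 9`). The
system closes with the Young-Laplace tube law `P = G0 (sqrt(A/A0) - 1)`,
`G0 = sqrt(pi) h0 E / ((1-nu^2) sqrt(A0))`, `nu = 1/2`. Note the friction
term is implemented exactly as the source model prints it, i.e. *without*
the factor `pi` that most 1D-haemodynamics derivations carry; at these
Reynolds numbers the difference is a few percent of an already small
viscous correction.

*Density.* The source model prints `rho = 1.028e-3 g/cm^3`, which is three
orders of magnitude below the density of blood in CGS units. The package
default is `1.028 g/cm^3`; the choice is exposed as the `rho` argument of
`build_arterial_network()` and echoed into every run manifest.

*Scheme.* An explicit, conservative, cell-centred Richtmyer two-step
Lax-Wendroff method (second order in the interior), fixed time step at
CFL <= 0.9 against the resting characteristic speed
`c(A) = sqrt(G0/(2 rho) sqrt(A/A0))` with 200 cm/s of advective headroom.
Because the update is in flux form, the discrete volume `sum(A dz)`
changes exactly by the boundary fluxes; closed single-vessel tests
conserve it to machine precision, and the full network balances volume
against the inlet/outlet flux integral to well under 0.5 % per beat.

*Boundaries.* Junctions of any degree (including the merging vertebral
junction, the internal-carotid trifurcations, and the loops of the circle
of Willis) are closed by a damped Newton solve (max 50 iterations,
relative tolerance 1e-10, warm-started from the previous step) of the
outgoing characteristic invariants `u +- 4c`, signed mass conservation and
equality of total pressure `P + rho/2 (Q/A)^2`. The aortic inlet
prescribes the half-sine beat `Q_max sin(pi t / 0.3 T)` for the first 30 %
of each period (`T = 1 s`, `Q_max = 485 cm^3/s`). Each outlet carries an
RCR Windkessel advanced by implicit Euler.

*Windkessel calibration.* Total peripheral resistance is sized to a mean
arterial pressure target (default 93 mmHg over 5 mmHg venous) at the mean
inflow `0.3*(2/pi)*Q_max`, and distributed over the outlets by
cross-section-area weighting. Because the 1D path resistances would
otherwise skew that split, the outlet resistances are corrected by a fixed
point against a steady resistive surrogate of the network, so the
beat-averaged flow split is area-weighted *exactly*. `R1` is the
characteristic impedance `rho c(A0)/A0` (capped at 20 % of the total) and
`C` follows from a configurable diastolic decay time (default 1.3 s).

*Vessel table.* Only six vessels (14, 17, 34-37) are fully specified by
the source model; the remaining 31 ship in
`inst/extdata/vessels37.csv` with provenance tag `"literature"`,
reconstructed from the classic circle-of-Willis compilation the model
cites. This is the dominant uncertainty in the package: the averaged
coupling flow at the brainstem branch evaluates to about 0.40 cm^3/s
against the reported 0.46, the difference being exactly the outlet-area
share of the branch in the reconstructed table.

## Mesoscale Murray tree

Radii across one symmetric bifurcation obey `r_l = 2^(1/gamma) r_(l+1)`
(default `gamma = 3`, configurable in [2, 3.5]), so a leaf of radius `r_c`
fed from a root of radius `r0` carrying `Q0` receives
`Q = Q0 (r_c/r0)^gamma`. The number of levels `gamma log2(r0/rn)` is
generally non-integer and never rounded: only the radius-ratio power law
is used downstream. `Q0` is the trapezoidal average of the feeding-vessel
outlet flow over one periodic beat. Outlet flows of the capillary bed are
distributed by cross-section area so that mass is conserved exactly.

## 3D-1D microcirculation

On the capillary centre lines the axial flux `-pi R^2 K1 dp1/ds` balances
the wall exchange `2 pi R Lp (p1 - p3bar)`; in the tissue box a Darcy flux
`-K3 grad p3` balances the matching line source. Units are um, mmHg, s.
Defaults: `K1` Poiseuille (`R^2/(8 mu)` with the shared diameter-dependent
viscosity interface), `K3 = 1 um^2/(mmHg s)` and `Lp = 1e-3 um/(mmHg s)`
as literature-placeholder config constants (the source model cites but
does not print them).

*Discretisation.* Node-centred finite volumes on the graph, uniform-grid
finite volumes in the box. The cylinder-surface averaging operators are
realised by nearest-cell quadrature: each segment is subdivided at the
grid pitch, each sub-point couples its interpolated line pressure to its
containing cell. The coupled matrix is symmetric; prescribed inlet and
outlet fluxes are Neumann data that must balance, and the pure-Neumann
nullspace is fixed by a single pinned unknown, after which all pressures
are shifted uniformly so the length-weighted network mean hits the 30 mmHg
gauge. When `Lp = 0` decouples the tissue block, both sub-systems are
pinned; a `cell3d` gauge supports deliberately throttled-outlet
experiments in which the excess flow must exit through the vessel walls.

*Transport.* Operator splitting: explicit upwind advection on the graph
and on grid faces, explicit antisymmetric wall exchange, implicit
diffusion (sparse solve), homogeneous Neumann outer boundary. A closed
system conserves tracer mass to the linear-solver tolerance.

*Synthetic geometry.* The bundled generator emulates the layout of the
reconstructed cortical block the model builds on (150 x 160 x 140 um, two
inlets of radii 4.5 and 4.0 um): two binary trees with exact Murray radii
grow from opposite faces, opposing leaves are joined by anastomoses, and
two leaves are routed to the boundary as outlets. It reproduces the
*format and statistics* of such data, not any real topology; green micro
tests therefore establish correctness of the solver contracts, not
anatomical fidelity.

## 0D cellular chain

The fast block (RK4/exact-exponential/Euler at 0.01 ms) contains, per
transmitter system (Glu and GABA with their distinct constants):
Hodgkin-Huxley spiking (classic squid kinetics shifted to -70 mV rest);
an N-type channel (two-gate Boltzmann activation, Nernst reversal from
2 mM external calcium); fast bouton calcium with a Michaelis-Menten
plasma-membrane pump and inward leak; a modified Li-Rinzel ER subsystem
with dynamic ER calcium (`dc_ER/dt = -(1/c1) dc_slow/dt`) and
glutamate-driven IP3 production (0.3-order Hill); a 7-state vesicle sensor
(5 sequential calcium bindings + isomerisation) simulated by exact SSA for
the two docked vesicles; Poisson spontaneous release; Tsodyks-Markram
pools with release lockout (6.34 ms Glu, 7.2 ms GABA) and vesicular
concentrations 60 / 20 mM.

The slow block (0.1 ms) advances the stochastic astrocyte G-ChI model
(IP3R gate noise with variance `(alpha(1-h)+beta h)/N_IP3`, cluster size
20, Euler-Maruyama, projection to [0,1] after the kick), the three
gliotransmitter gates (dissociation 108/400/800 nM, closure 2.5/1/0.1 s),
the postsynaptic potential (AMPA/NMDA/GABAa/GABAb conductances), the NO
pathway (NMDA-weighted calcium current `0.63 w_NR2A + 11 w_NR2B` driving a
first-order nNOS activation; eNOS with calcium- and wall-shear-stress
terms, shear from Hagen-Poiseuille `4 mu Q/(pi R^3)`; a four-compartment
Einstein-Smoluchowski diffusion chain with `tau = dx^2/(2D)`, `dx = 25 um`,
production zero in astrocyte and SMC; first-order scavenging), soluble
guanylyl cyclase producing cGMP, the SMC/EC pair (linearised heterocellular
exchange of Ca, voltage, IP3; KIR flux with the fitted Nernst line
`v_KIR = z1 K_p - z2`; a BK channel whose activation curve is shifted in
voltage by `c_w = 1/(eps + alpha exp(gamma cGMP))`, `gamma < 0` so cGMP
promotes opening), the Hai-Murphy four-state cross-bridge scheme with
`K1 = K6 = gamma_cross Ca^3` and cGMP-regulated dephosphorylation
`K2 = K5 = delta (k_b + k_c R_cGMP)`, and the Kelvin-Voigt wall
`dR/dt = (R0_pas/eta)(10 dp - E(F_r)(R - R0(F_r))/R0(F_r))` with
`h = 0.1 R` making the pressure term the constant `10 dp`.

*Parameter provenance and calibration.* Every constant ships in the
registries `inst/params/synapse_defaults.csv` and `nvc_defaults.csv` with
a `source` tag (`paper` / `literature` / `calibrated`). As in the source
model, a handful of rates are determined by iteration rather than
measurement, and `calibrate_rest()` performs that calibration
reproducibly: the PMCA ceiling `v_PM_Ca` and SERCA ceiling `v3` are solved
so that the resting state (`c_i = 0.1 uM`, `c_ER = 120 uM`) is an exact
fixed point. The resting ER level, the ER leak `v2`, the
extrasynaptic-release pair (`n_av`, `g_ac`) and the SMC balance
(`F_i`, `k_ex_i`, `B_i`) were fixed once so that the post-transient ER
trajectory sits inside the experimentally reported 60-270 uM band, the
extrasynaptic glutamate stays near 0.1 mM, SMC calcium oscillates gently
around 0.2 uM, and capillary radius excursions remain inside a +-5 %
physiological envelope. These are statements about the default *regime*,
not fitted outputs; the tests that check them use fresh simulations.

*Randomness.* All stochastic components draw from R's RNG (named
sub-processes would be overkill at this size); `set.seed()` before
`simulate_ngvu_cell()` reproduces a trace bit for bit.

*Cross-implementation check.* The per-term R functions are the documented
reference; the long-horizon integrator is compiled. A test advances both
over a 50 ms deterministic window and requires agreement to 1e-6.

## Sensitivity analysis

The response metric is the amplitude of the post-transient radius
oscillation: with `T0 = 5 s` and `t_end = 60 s`, `Rbar` is the trapezoidal
time-weighted mean of `R(t)` over `[T0, t_end]` and
`A = max |R(t) - Rbar|`; results are reported as
`DeltaA = 100 (A/A0 - 1)` per cent. Three designs are provided: OAT (ten
equally spaced factors over [0.7, 1.3], one parameter at a time), global
LHS (default N = 200, independent stratified columns over +-30 %
hyperrectangles) summarised by partial rank correlation coefficients
(residual-correlation construction on average ranks), and tornado local
elasticities from symmetric +-10 % central differences. The probed
parameters are the wall triplet (`dp`, `E_act`, `E_pas`); the viscoelastic
damping `eta` is held fixed to avoid stiffness-damping confounding.

*Default model runner.* Integrating the full stochastic chain for every
one of the ~240 design points would take hours; the default runner
therefore integrates only the cross-bridge + wall subsystem under a frozen
periodic SMC-calcium/cGMP drive whose level and excursion emulate the
coupled chain's post-transient regime (10 s period, Ca 0.35 +- 0.15 uM,
cGMP 4 +- 1.5 uM). This is the "stochastic components frozen to a common
seed" protocol taken to its cheap limit: parameter draws differ only
through the wall mechanics. Any runner with the same interface (named
parameter vector in, `t_s`/`R_um` data frame out) can be substituted, so
full-chain studies remain possible. With the frozen drive the diagnostics
reproduce the expected structure: `dp` dominant and positive, both moduli
negative, `|E_act| > |E_pas|`, and all three diagnostics agreeing in sign.

## Orchestration

`run_full_simulation()` implements the per-heartbeat workflow: the macro
stage runs once to periodicity (beat-to-beat relative L2 difference of
pressure and flow below 1e-3 at all monitored outlets) and its averaged
`Q0` is reused for all beats; per beat, the cellular chain advances one
period, the end-of-beat radius rescales the capillary radii (conductance
following the configured Poiseuille law, so segment conductance scales
with `R^4`), and the stationary 3D-1D pressure problem is re-solved
(quasi-static coupling, matching the stationary microcirculation model).
No micro-to-macro back-coupling is implemented. The manifest (seeds,
provenance warnings including the density note, timings, field ranges) is
written before any stage output. Cellular state other than the wall radius
is re-initialised each beat; over the one-second horizon of a beat this
truncates slow astrocytic memory, a documented simplification of the
quasi-static coupling.

## Known limitations

- The vessels-1-33 table is a literature reconstruction; headline macro
  quantities inherit its uncertainty (see the package README).
- The 1D scheme is not shock-capturing (no limiter); physiological beats
  are smooth enough that this never binds.
- The micro transport module is a generic advection-diffusion-exchange
  solver; oxygen-haemoglobin binding, haematocrit partitioning and
  red-cell phase separation are out of scope.
- GABA receptor currents mirror the AMPA/NMDA conductance forms with
  inverted reversal potentials; the source model gives no separate
  equations for them.
- The BK baseline open-probability law and the nNOS activation functional
  are parameterised first-order stand-ins for cited (unprinted) forms;
  their direction of effect is unit-tested.
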