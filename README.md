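# ngvu

Multiscale simulation of the neuro-glial-vascular unit (NGVU): the
functional ensemble of neurons, astrocytes, smooth-muscle and endothelial
cells and the brain vessel they regulate. The package is aimed at
computational physiologists who want a desk-scale, fully scripted model of
functional hyperemia — from systemic pulsatile haemodynamics down to
synaptic calcium — with every coupling step testable in isolation.

## What it computes

- **1D-0D macrocirculation** — nonlinear 1D blood flow
  (`∂ₜA + ∂_zQ = 0`, momentum with Young–Laplace tube law
  `P = G₀(√(A/A₀) − 1)`) on a 37-vessel network (aorta → circle of Willis
  → two brainstem branches), half-sine cardiac inflow
  (`T = 1 s`, `Q_max = 485 cm³/s`), RCR Windkessel outlets, run to a
  periodic state.
- **Mesoscale Murray tree** — the beat-averaged outlet flow `Q₀` of the
  feeding vessel maps to capillary inlet flows via
  `Q = Q₀ (r_c/r₀)^γ` (default `γ = 3`).
- **3D-1D microcirculation** — stationary coupled pressures
  `−π R²∂ₛ(K₁∂ₛp₁) + 2πR L_p(p₁ − p̄₃) = 0` on the capillary graph,
  `−∇·(K₃∇p₃) + L_p(p₃ − p₁)δ_Γ = 0` in the tissue box, velocities
  `v = −K∇p`, plus advection–diffusion transport; a synthetic
  brain99-style network generator is bundled.
- **0D quadripartite synapse + neurovascular coupling** —
  Hodgkin–Huxley spiking, bouton calcium (N-type influx + Li–Rinzel ER),
  stochastic vesicle sensors and Tsodyks–Markram pools, astrocyte G-ChI
  calcium with gliotransmission, NO/cGMP signalling, KIR and BK channels,
  Hai–Murphy cross-bridges (`K₁ = K₆ = γ_c Ca³`), and a Kelvin–Voigt wall
  `dR/dt = (R₀p/η)(10Δp − E(F_r)(R − R₀(F_r))/R₀(F_r))` that feeds the
  radius back into the microcirculation.
- **Sensitivity analysis** — post-transient radius amplitude
  `A = max|R(t) − R̄|` under OAT sweeps, Latin-hypercube sampling with
  PRCCs, and tornado elasticities for (`Δp`, `E_act`, `E_pas`).

## Worked example

```r
library(ngvu)

## macro: run the arterial network to a periodic state (~25 s)
net <- build_arterial_network()
macro <- run_to_periodicity(net, couple_vessel = 37)
macro$Q0
#> [1] 0.4048445          # beat-averaged flow at the brainstem branch, cm^3/s
range(macro$P_out_mmHg)
#> [1]  70.88239 110.89510  # physiologic diastolic/systolic envelope

## meso: capillary inlet flows at the reported coupling flow Q0 = 0.46
meso <- mesotree_couple(0.46, c(4.5e-4, 4.0e-4), r0 = 0.08, gamma = 3)
meso$inlets
#>   radius_cm       Q_cm3s     v_cms
#> 1   0.00045 8.187012e-08 0.1286917
#> 2   0.00040 5.750000e-08 0.1143926
```

The inlet flows 8.19e-8 / 5.75e-8 cm³/s and velocities 0.13 / 0.11 cm/s
land inside the 0.05–0.15 cm/s band reported for brain capillaries. The
package's own macro run gives `Q0 = 0.405` rather than the reported 0.46:
only six vessels of the network are fully specified by the source model,
and the remainder ship as a provenance-tagged literature reconstruction
(`inst/extdata/vessels37.csv`) whose outlet-area share at the brainstem
branch fixes this number (see the methods vignette).

```r
## micro: pressures and velocities on a synthetic capillary block
g   <- generate_synthetic_network(seed = 1, levels = 3)
dom <- tissue_domain(grid = c(8, 8, 8))
sol <- solve_pressure_3d1d(g, dom, inlet_flows = meso$inlets$Q_cm3s * 1e12)
c(mean_p1 = mean(sol$p1), residual = sol$residual)
#>      mean_p1     residual
#> 3.141010e+01 5.243446e-14

## cell chain: 60 s of the coupled synapse/vessel cascade (~9 s)
set.seed(1)
tr <- simulate_ngvu_cell(t_end_s = 60)
post_transient_metrics(tr$t_ms / 1e3, tr$R_um)
#> $Rbar            $A
#> [1] 20.83305     [1] 0.8644194  # ~4.1 % excursion: inside the +-5 % band

## sensitivity of the radius amplitude (frozen-drive wall runner)
local_elasticity()
#>         dp      E_act      E_pas
#>  0.3786150 -0.2066720 -0.1709939
```

The elasticity of the transmural pressure is the largest and positive;
both wall moduli act negatively with `|E_act| > |E_pas|` — pressure sets
the drive, active stiffness the gain, passive stiffness a smaller brake.

A full per-heartbeat workflow (macro → meso → cellular advance → radius
feedback → micro re-solve) is available as
`run_full_simulation(ngvu_config(...))`, or from the shell:

```sh
Rscript -e 'ngvu::ngvu_cli()' macro --tol 1e-3
Rscript -e 'ngvu::ngvu_cli()' sens --mode lhs --n 200 --seed 42
```

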