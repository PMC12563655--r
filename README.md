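# ionlattice

Field-gated anion transport in nanoparticle superlattices: a
Brownian-dynamics generator plus a trajectory-analysis pipeline for
studying how multivalent anions move through an FCC lattice of positively
charged nanoparticles (NPs) under a uniform electric field.

## Who this is for

Researchers in coarse-grained molecular modelling and nanoscale ion
transport who want a small, fully reproducible sandbox for the
phenomenology of counterion-mediated NP superlattices: electrophoretic
drive versus interfacial adsorption and steric confinement, and the
compartment-resolved kinetics that result. The analysis layer also works
on imported trajectories (extended-XYZ with periodic image flags; GRO).

## What it computes

One conventional FCC cell (4 NPs: one corner, three face centers) is
neutralized by one of four phosphate-like anion species — P2 (linear,
−4 e), P3 (ring, −3 e), P4 (linear, −6 e), P6 (ring, −6 e) — and driven
by a field **E** along x. The electrophoretic force is charge-proportional,
F = qE. On top of the simulator the package provides:

- **Compartments** — every anion geometric center is classified per frame
  as tetrahedral cavity (within 2.0 nm of FCC corner sites), octahedral
  cavity (within 2.5 nm of face-center sites) or NP–NP interface
  (remaining void), with minimum-image distances.
- **Residence kinetics** — continuous residence events per compartment,
  survival curves C(t) = N(t)/N₀, double-exponential fits
  C(t) = A₁e^(−t/λ₁) + A₂e^(−t/λ₂), and the amplitude-weighted mean
  residence time ⟨τ⟩ = (A₁λ₁ + A₂λ₂)/(A₁ + A₂).
- **Transition matrices** — row-stochastic lag-k compartment transition
  probabilities pooled over anions (rows summing to one; unvisited rows
  reported as undefined).
- **Transport** — per-anion drift velocities, ionic current
  I = (1/Lₓ) Σ qᵢv̄ₓᵢ, current density, conductivity and resistivity.
- **Density maps** — 3D-binned anion centers projected on X–Y and
  normalized by the global maximum of the map set.
- **Sweeps** — `run_sweep()` orchestrates simulate → classify → kinetics /
  transitions / transport / density over a species panel and field grid
  with per-condition seeds and reproducible CSV/JSON reports.

## Worked example

```r
library(ionlattice)
cfg  <- build_config("P3", field = 0.3, seed = 1)   # 80 anions neutralize +240 e
traj <- run_bd(cfg)
labels <- classify_trajectory(traj)
labels
#> Label series: 80 anions x 301 frames (dt = 0.5)
#>   occupancy O 0.290 | I 0.611 | T 0.099

transition_matrix(labels, lag = 1)
#> Transition matrix (lag 1, frame mode), rows sum to 1:
#>       O     I     T
#> O 0.951 0.049 0.000
#> I 0.024 0.969 0.006
#> T 0.000 0.034 0.966

v <- axial_velocities(unwrap(traj))
ionic_current(v, cfg$species, cfg$lattice$box, field = 0.3)
#> Transport at E = 0.3 V/nm (80 anions): v = -0.2541 +/- 0.0034 nm/tau,
#>   I = 6.099 e/tau, rho = 4.919
```

The occupancy line says where the 80 trimetaphosphate anions spend their
time (61% in the interparticle void, 29% near octahedral/face sites, 10%
near the corner site). The transition matrix shows strong frame-to-frame
confinement (diagonal ≥ 0.95 at this field and save interval). The mean
drift of −0.254 nm/τ against +x (anions are negative) carries a
conventional current of +6.1 e/τ through the cell. Residence-time fits
per compartment come from `residence_times(labels)`.

All quantities are in reduced units (length nm, energy k_BT, time from
the bead friction); fields are stated in V/nm and converted by a
documented energy-scale constant. See the methods vignette
(`vignettes/field-gated-anion-transport.Rmd`) for the model, the
calibrated defaults and known limitations.

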