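# poredyn

Analysis of water and ion dynamics confined in transmembrane
self-assembled cyclic peptide nanotube (SCPN) channels.

SCPNs are stacks of cyclic peptide rings held together by inter-ring
backbone hydrogen bonds; inserted in a lipid bilayer they form hollow
channels whose confined solvent is strongly structured — angularly
modulated density lobes in the transverse plane, axial alternation between
ring planes and inter-plane regions, and residence times that differ by
species. poredyn is for molecular-simulation practitioners who have such
trajectories (or want a controlled synthetic stand-in) and need the
standard battery of confined-species analyses as tested, reusable code.

## What it computes

- **Residency**: a particle is inside the pore at a frame when its radial
  distance from the fitted channel axis satisfies `R ≤ pore_radius` and
  its axial projection lies within the padded backbone extent. Occupancy
  counts, per-particle z-traces, and z-presence histograms follow from the
  residency matrix.
- **Survival probability and residence half-life**: for lag τ,
  `P(τ) = ⟨ N(t, t+τ) / N(t) ⟩_t` over time origins t with N(t) > 0, where
  N(t) is the number of tracked particles inside at t and N(t, t+τ) the
  number of those still inside after τ (under the default continuous
  convention, inside at every stored frame in between). The residence
  half-life τ₁/₂ is the lag at which P crosses 0.5, linearly interpolated.
- **Windowed velocities**: finite-difference mean velocities over fixed
  windows (default 10 ps) for particles that stay inside throughout the
  window, unwrapped across periodic boundaries and tagged with the
  start-of-window position; speed distributions use Freedman–Diaconis
  binning (`2·IQR·n^(−1/3)`), and position–velocity maps correlate speed
  with (R, θ).
- **Density maps**: positional probability heatmaps (counts / total inside
  counts) in channel-aligned XY/XZ/YZ planes and on the (R, θ) grid, with
  time-averaged backbone overlays; maps always sum to 1.
- **Solvation structure**: contribution-decomposed radial distribution
  functions `g_c(r)` normalized by centers, contributors, and ideal shell
  density; first coordination-sphere radii from the first post-peak
  minimum; coordination numbers by direct counting cross-checked against
  `4πρ∫ g(r) r² dr`.
- **Hydrogen bonds**: geometric criterion (D···A ≤ 3.5 Å,
  D–H···A ≥ 150°), per-frame counts, and the theoretical inter-ring
  maximum `(n_rings − 1) × bonds_per_interface`.
- **Synthetic ground truth**: overdamped Langevin particles in a
  star-modulated cylindrical pore, an exponential dwell process with known
  half-life, and a Boltzmann rejection sampler of the same pore potential
  — every analysis above is validated against these generators.

Units are angstrom and picoseconds throughout. Inputs: a plain-text
fixture trajectory dialect, GRO/PDB topologies, DCD frames (via bio3d);
XTC/TRR are not supported.

## Worked example

Recover a known residence half-life from a synthetic dwell process, then
check the angular structure of a confined Brownian run:

```r
library(poredyn)

sim <- simulate_dwell_process(dwell_process_params(
  lambda_in = 0.05, lambda_out = 0.05, n_particles = 120,
  duration = 2500, seed = 42))
sv <- survival_probability(sim$res, tau_max = 100)
sv
#> <poredyn_survival> continuous convention, 101 lags, tau_half = 14.49325 ps

log(2) / 0.05   # ground truth
#> [1] 13.86294

p <- pore_model_params(dt = 0.05, seed = 1)   # order-6 star, R0 = 9 A
run <- simulate_confined_brownian(p, n_particles = 100, duration = 500)
geom <- fit_channel_axis(run$traj, "backbone", pore_radius = 9, z_pad = 2)
res <- classify_inside(run$traj, geom, "tracked")
occupancy_stats(res)$mean
#> [1] 81.51331

cm <- cylindrical_heatmap(run$traj, res, geom, r_bins = 9, theta_bins = 36)
sum(cm$prob)
#> [1] 1

theoretical_max_hbonds(8, 12)
#> [1] 84
```

The recovered half-life (14.49 ps) sits within 5% of the exponential
ground truth ln(2)/λ = 13.86 ps at this sampling; the angular Fourier
spectrum of the same run peaks at harmonic 6, the order of the imposed
star potential.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full study on synthetic data, writing tables under `results/`:

1. `01_simulate.R` — generate the confined-Brownian trajectory and
   per-species dwell residencies (ground truth to `ground_truth.json`).
2. `02_occupancy_survival.R` — occupancy, z-histograms, survival curves
   and half-lives per species.
3. `03_velocity.R` — 10-ps windowed velocities, FD speed histogram,
   speed-vs-R profile.
4. `04_maps.R` — XY/XZ and (R, θ) probability heatmaps, backbone overlay,
   angular spectrum.
5. `05_coordination_hbonds.R` — decomposed RDF, first-shell radius,
   coordination table (both routes), H-bond counts and the 84-bond
   theoretical maximum.

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript "$s"; done`

A configuration-driven one-shot interface is also available:
`run_full_analysis(config)` executes any subset of stages from a single
YAML/list config (see `?validate_config`) and writes a JSON report with
the config hash and seed.

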