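---
title: "Methods: confined water and ion dynamics in peptide nanotube channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confined water and ion dynamics in peptide nanotube channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Self-assembled cyclic peptide nanotubes (SCPNs) are stacks of peptide rings
held together by inter-ring backbone hydrogen bonds; inserted in a lipid
bilayer they form hollow transmembrane channels through which water and
ions move. Trajectories of such systems show strongly structured confined
solvent: angularly modulated density ("star" patterns set by the ring
chemistry), axial alternation between ring planes and inter-plane regions,
and species-dependent residence times. poredyn implements the analysis
pipeline for this setting — residency, survival, velocities, density maps,
solvation structure, hydrogen bonds — together with a synthetic generator
that reproduces the statistical structure those analyses assume, so every
stage can be validated against known ground truth.

All lengths are angstrom and all times picoseconds, everywhere. GRO input
(nm) is converted on load. Particle indices in the R API are 1-based.

## Channel geometry

The channel axis is fitted per frame as the principal axis (leading
eigenvector of the centered second-moment tensor) of the backbone atom
group, with the sign aligned frame-to-frame so the axis never flips; the
origin is the backbone centroid and the axial extent is the backbone
projection range padded by `z_pad` (default 2 A). A laboratory-fixed axis
(`mode = "lab_z"`) is available for systems prepared with the tube along
z; the fitted axis is the default because it tolerates tube tilt and
drift.

Angular coordinates need a reference direction. By default the laboratory
x-axis is projected onto the transverse plane; if a `theta_ref_group` is
given, the in-plane direction toward that group's centroid is used
instead, giving a frame that co-rotates with the tube. Co-rotation matters
for long averages: without it, tube rotation smears the angular lobes of
the density maps. On-axis points get `theta = 0` by convention; `theta`
lives in `[-pi, pi)`.

A particle is *inside* the pore at a frame when its radial distance
satisfies `R <= pore_radius` and its axial projection lies within the
padded backbone extent. The pore radius is a configuration value (default
9 A, the nominal inner radius of the alpha,delta-type channel), not
inferred from data; water is represented by its oxygen site, ions by the
ion site.

## Survival probability and residence half-life

For lag tau, the survival probability averages, over time origins t with
at least one particle inside, the fraction of particles inside at t that
are still inside at t + tau:

    P(tau) = < N(t, t + tau) / N(t) >_t

Under the default **continuous** convention, N(t, t+tau) counts particles
inside at *every stored frame* of [t, t+tau]; a particle that exits and
re-enters does not survive. This is the strict residence convention: it
makes P non-increasing and P(0) = 1. The **intermittent** convention
(inside at both endpoints only) is available by flag.

Two origin policies are provided. `origins = "fixed"` (default) uses the
same origin set `t <= T - tau_max` for every lag, which makes the
continuous-convention curve *exactly* monotone — the natural reading of a
fixed 1/T prefactor. `origins = "per_tau"` admits every origin with
`t + tau <= T`, using more data at short lags; because the origin set then
shrinks with tau, small upticks can appear at long lags where few origins
remain, so monotonicity holds only statistically. Origins with N(t) = 0
are always excluded, keeping P(0) = 1 exact. The default `tau_max` is half
the trajectory span so that origins remain plentiful at the longest lag.

The residence half-life tau_1/2 is the lag at which P crosses 0.5, linearly
interpolated between the bracketing grid points; if P never reaches 0.5
the half-life is reported as undefined (`NA`), not an error. Exponential
dwell kinetics with exit rate lambda give tau_1/2 = ln(2)/lambda, which is
the recovery target for the synthetic dwell process.

## Windowed velocities

Mean velocities are finite differences over fixed windows (default 10 ps,
non-overlapping; stride configurable): displacement across the window,
unwrapped by accumulating minimum-image frame-to-frame steps, divided by
the window length, and associated with the start-of-window position. A
window is kept only if the particle is inside the pore at every frame of
the window, so bulk motion never contaminates the confined statistics.
Non-overlapping windows avoid autocorrelated samples; the estimator is
exact for linear motion at any window length, and for free diffusion the
mean windowed speed scales as `window^(-1/2)` (a useful self-check that
the samples are diffusive rather than ballistic).

Speed histograms use the Freedman-Diaconis width `2 IQR n^(-1/3)` with the
linear-interpolation quantile convention (`stats::quantile` type 7 — FD
widths are convention-sensitive, so the convention is fixed and
documented). Zero-IQR samples fall back to Scott's normal-reference width;
fully constant samples produce a single bin.

## Density maps

Positional probability maps are raw count fractions: counts of
inside-particle positions on a regular grid (channel-aligned XY, XZ, YZ
planes at 0.25 A default bin width, or an (R, theta) grid), divided by the
total number of inside counts, so every map sums to 1. No 1/R Jacobian
correction is applied on the cylindrical grid — the quantity is the
probability of positions, not a number density; the corrected variant is
available by flag. The default planar bin width resolves ~1 A features
(the angular lobes) without empty-bin noise at the sampling densities the
generator produces. Backbone overlays are time-averaged atom positions in
the same channel-aligned (co-rotating) frame.

## Solvation structure and hydrogen bonds

The decomposed RDF for centers (e.g. a cation species, restricted to
inside frames) against each contributor class c is

    g_c(r) = <pair counts in [r, r + dr)> /
             (n_center_obs * n_contributors_c * V_shell / V_box)

with minimum-image distances; the normalization metadata (center
observations, contributor counts, shell volumes, box volume) is stored so
any alternative normalization can be recomputed. A uniform contributor gas
gives g = 1 at every shell — the bulk limit used as a test.

The first coordination-sphere radius is the first local minimum of a
3-point moving-average smoothed g(r) after the first peak; the peak must
exceed 1 *and* reach half the global maximum. The prominence requirement
exists because a single close approach in an otherwise empty small-r shell
yields a large g value purely through the tiny shell volume in the
denominator, and the minimum right after such a spike is spurious.

Coordination numbers are counted directly (contributors within the shell
radius of each inside center, mean and SD over all (frame, center)
observations — the SD convention is per observation, not per frame or per
ion) and cross-checked against `4 pi rho int_0^rs g(r) r^2 dr` computed
from the matched RDF; the two routes agree within 2% on uniform-gas
fixtures by construction of the shared normalization.

Hydrogen bonds use the common geometric criterion: donor-acceptor distance
at most 3.5 A and donor-hydrogen-acceptor angle at least 150 degrees, both
configurable. The theoretical maximum of inter-ring backbone H-bonds for a
tube of n stacked rings with b bonds formable per adjacent-ring interface
is `(n - 1) * b` — 84 for the eight-ring tube with 12 bonds per interface.

## The synthetic generator

The generator is a stand-in for all-atom production runs, not a physical
model of the peptide. Overdamped Langevin dynamics (Euler-Maruyama, kT
units)

    x <- x + D(x) F(x) dt + sqrt(2 D(x) dt) xi

run in a cylindrical pore with a harmonic soft wall
`0.5 k (R - R0)^2` beyond the pore radius and a modulation potential

    U = -A_theta (R/R0)^2 cos(k theta) - A_z cos(2 pi z / period)

The `(R/R0)^2` factor keeps the angular force regular on the axis and
concentrates the angular structure near the wall, where the star lobes sit
in the real system. Defaults mirror the study geometry: pore radius 9 A,
eight 4.9-A axial periods (39.2 A channel), harmonic order 6, angular
amplitude 1.5 kT, axial amplitude 1 kT, water-like D = 0.23 A^2/ps,
wall stiffness 5 kT/A^2, timestep 0.02 ps, frames saved every 1 ps.
Axial boundaries are reflective by default (periodic by flag). An optional
mobility ramp scales D down linearly from 0.7 R0 to the wall; this uses a
plain Euler-Maruyama step without the spurious-drift correction for
position-dependent diffusion, so the mobility-varying configuration is
used for qualitative inner-versus-outer speed contrasts, not for
quantitative equilibrium-density claims. A stability guard rejects
timesteps for which the wall force would move a particle more than 0.5 A
per step at 1 A overshoot (`D k dt > 0.5`).

Because the wall is soft, saved positions penetrate beyond R0 with
Boltzmann depth `1/sqrt(k)` (~0.45 A at defaults); the confinement
guarantee is `R <= R0 + 5/sqrt(k)` plus one step's noise, not a hard cut.

The dwell process alternates outside/inside states per particle with
exponential waiting times (rates lambda_in, lambda_out), sampled onto the
frame grid; the continuous intervals are recorded as ground truth, and the
expected-event count is flagged when below 50. The Boltzmann sampler
draws positions from `exp(-U)` by rejection over the pore volume
(radially out to three wall standard deviations, matching the Brownian
marginal) and is the equilibrium reference for the map tests.

All three generators take an integer seed and are bitwise reproducible;
they save and restore the caller's RNG state.

### What the generator does and does not emulate

It reproduces: confinement in a quasicylindrical pore, six-fold angular and
~4.9 A axial density modulation, exponential residence kinetics, diffusive
(not ballistic) short-time motion, species-dependent mobility. It omits:
electrostatics and ion-ion coupling, lipid membranes, hydrogen-bond
network realism, backbone flexibility, and any force-field fidelity.
Passing tests therefore validate the *estimators* — that survival curves
recover known half-lives, maps recover known modulation, RDF machinery
recovers known structure — not any claim about real peptide chemistry.

## Numerical choices

- Axis sign continuity: first frame oriented toward +z, subsequent frames
  flipped to keep a positive dot product with the previous frame.
- Degenerate inputs: a coincident backbone point cloud is an error; a
  point on the axis gets theta = 0; empty analysis windows and empty maps
  are errors naming the condition.
- The tau grid is every multiple of the frame spacing up to `tau_max`;
  `tau_max` beyond the span is an error.
- RDF smoothing before minimum detection: 3-point moving average,
  width configurable.
- Histogram conventions: left-closed bins (`[lo, hi)`), rightmost closed.
- Problem sizes in the test suite are chosen for sub-minute module tests
  (hundreds of particles, 1-2.5 ns synthetic runs, ~10^5 Boltzmann
  samples); parameter-recovery tolerances (10% on half-lives, 15% on
  diffusive scaling, total-variation 0.05 between generator and sampler
  maps) reflect the statistical error at those sizes.

## Input formats and limitations

Supported inputs: the plain-text fixture dialect (header
`n_frames n_particles dt_saved box_x box_y box_z`, then frame blocks of
`x y z` lines), GRO and PDB topologies, and DCD frame files (via bio3d).
XTC/TRR are not supported — no R reader exists for them; convert to DCD or
the fixture dialect upstream. Boxes are orthorhombic; triclinic cells,
trajectory alignment/RMSD fitting, MSD-based diffusion estimation and
velocity autocorrelation are out of scope.
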