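---
title: "Winner-take-all competition between Cdc42 polarity peaks: model, analyses and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winner-take-all competition between Cdc42 polarity peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarcomp)
```

## The model

Budding yeast commits to a single growth site by concentrating active
(GTP-bound) Cdc42 into one membrane cluster. `polarcomp` simulates a
mass-conserved membrane–cytosol reaction–diffusion model of this process
and implements the analyses that explain why several nascent clusters
resolve into a single front: clusters compete for shared, rapidly
exchanging cytoplasmic pools, and the largest cluster wins.

Four membrane species live on a square periodic grid (a torus) of area
$A = 25\pi\,\mu m^2$: GTP-Cdc42 (`Cdc42T`), membrane GDP-Cdc42
(`Cdc42Dm`), the membrane-associated Bem1–GEF complex (`BemGEFm`) and the
complex bound to GTP-Cdc42 (`BemGEF42`). Two well-mixed cytosolic pools,
GDP-Cdc42 (`Cdc42Dc`) and Bem1–GEF (`BemGEFc`), close the mass balance.
The kinetics are mass-action: GEF-catalysed nucleotide exchange
($k_{2a}, k_3$), first-order GAP hydrolysis ($k_{2b}$), GDI shuttling of
GDP-Cdc42 ($k_{5a}, k_{5b}$), Bem1–GEF membrane exchange ($k_{1a},
k_{1b}$), binding of membrane complex to GTP-Cdc42 ($k_{4a}, k_{4b}$) and
direct recruitment of cytosolic complex by GTP-Cdc42 ($k_7$). Positive
feedback arises because GTP-Cdc42 recruits GEF, which creates more
GTP-Cdc42. All membrane species diffuse with the same coefficient
$D_m = 0.0025\,\mu m^2/s$; the Bem1–GEF attachment flux carries Gaussian
white noise of strength $s = 10^{-4}$, applied mass-neutrally against the
cytosolic pool.

Two conventions deserve emphasis:

* **Units.** All concentrations are in µM. Membrane fields are *shell*
  concentrations, so a polarized peak reaches hundreds of µM while the
  conserved totals (1 µM Cdc42, 0.017 µM Bem1–GEF) are cytosol-equivalent:
  `total = eta * mean(membrane fields) + cytosol pool`, with
  `eta = 0.01` the membrane-to-cytoplasm volume ratio. This is the only
  reading under which the printed parameter table closes both conservation
  laws dimensionally, and the package's conservation tests hold to
  rounding error.
* **Sign conventions.** The published typeset equations contain
  typesetting slips (a detachment term printed with the wrong sign, one
  diffusion term printed negative, species labels shuffled between two
  equations). The implementation uses the unique sign assignment
  consistent with the reaction table and with mass conservation; the
  algebraic conservation identities are asserted in the test suite on
  random states.

## Numerics

The stiffness of this system is *not* where reaction–diffusion codes
usually expect it. With $D_m = 0.0025\,\mu m^2/s$ and the default grid
($N = 64$ on $L = \sqrt{25\pi} \approx 8.86\,\mu m$, $h \approx
0.138\,\mu m$) the explicit diffusion bound is $h^2/4D_m \approx 1.9$ s —
harmless. The fast rates are chemical and local: inside a peak
`k4a * Cdc42T` reaches several thousand per second, while in the
background it is ~10/s. The default stepper therefore advances diffusion
explicitly at a macro step (`dt = 0.02` s) and integrates the reactions
pointwise with *per-grid-point adaptive substepping*: each point takes
`ceil(dt * Lmax / theta)` forward-Euler substeps, where `Lmax` is its
largest local loss coefficient and `theta = 0.2`. Only the few hundred
peak-interior points are expensive; an implicit-diffusion scheme would
address the cheap part of the problem and was not adopted. A plain
global-step Euler–Maruyama stepper is retained and tested against the
adaptive one at small `dt`.

This splitting keeps both conservation laws *exact* (to floating-point
rounding): every bilinear reaction term is evaluated once per substep and
applied with opposite signs to its source and sink; membrane–cytosol
transfer is accumulated per substep and applied to the pools with the
`eta/A` weight; the noise increment added to `BemGEFm` is removed from
`BemGEFc` in the same step. The 600-s conservation criterion (< 0.1%
drift) is met at machine precision rather than by tuning.

Further numerical choices: tiny negative concentrations from the explicit
substeps are clamped only below $10^{-9}$ µM and abort the run above;
the homogeneous steady state is found by relaxing the well-mixed
six-species ODE system and polishing with Newton iteration on the
analytic Jacobian; grid-refinement (N = 48 vs 96 changes the relaxed
single-peak height by < 1%) and determinism (bit-identical trajectories
per seed) are tested.

## The competition experiment

At the published parameter set the homogeneous steady state is *linearly
stable*: the dispersion relation (4×4 membrane Jacobian minus $D_m q^2$,
the well-mixed cytosol cannot respond to zero-mean modes) has negative
leading eigenvalues at every admissible torus wavenumber. Polarization at
these parameters is excitable rather than Turing-driven: a
finite-amplitude seed (defaults: Gaussian bumps of 20 µM on `Cdc42T`,
s.d. 0.7 µm, with proportional `BemGEF42` and mass-neutral withdrawal
from the cytosol) grows into a stable peak, while the tiny attachment
noise alone does not nucleate. The defaults were chosen once for robust
convergence to the two-peak state and are not tuned per experiment. This
is consistent with how the competition experiment is defined — seeded
perturbations, not spontaneous onset — and the unstable-mode analyses
below use the abundance-corrected regime where a genuine Turing band
exists.

`run_competition_experiment()` seeds two identical bumps at antipodal
positions, relaxes noise-free for 300 s to the symmetric two-peak steady
state (mirror symmetry is preserved to $10^{-11}$, confirming the state
is a genuine unstable equilibrium), then switches the noise on.
Symmetry breaks within a few hundred seconds, after which the content gap
grows exponentially and the loser collapses; the coexistence clock runs
from noise switch-on (the unstable steady state) to the first snapshot
with a single surviving peak, matching how the model's competition time
courses are presented. A 60-s consolidation phase lets the winner absorb
the released material before final readouts. A peak is scored extinct
when its height falls below twice the homogeneous summed-membrane Cdc42
level — a threshold safely above the noise floor and far below any
genuine peak (~400 µM vs ~71 µM).

Flux accounting follows the peak's *waistline* — the circle around the
centroid where the azimuthally averaged summed membrane Cdc42
(`Cdc42T + Cdc42Dm + BemGEF42`) first falls to half its peak value.
Diffusive escape is the line integral $-D_m \oint \partial_r c\,dl$
evaluated from the interpolated radial profile; recruitment is the disc
integral of $k_{5a}\,Cdc42Dc - k_{5b}\,Cdc42Dm$, the model's only
membrane–cytosol Cdc42 exchange. At both the two-peak and the one-peak
steady states these balance within 5% (discretization, not model,
accounts for the residual: the Gaussian-field oracle shows the flux
estimator converging as the grid refines). Plotting both fluxes against
waistline content normalized to the final winner reproduces the
rate-balance picture: stable balance at the winner's content, unstable
balance near half that content where the symmetric two-peak state sits,
net loss below it and net gain above it.

## Dwell times and their quasi-steady-state laws

The retention analyses clamp one partner and follow a two-species linear
subsystem at the peak center; the package integrates these exactly
(eigendecomposition on a fixed grid of 2000 points spanning ten
closed-form half-times) and extracts half-times by interpolation. The
initial pool (70 µM Bem1–GEF; 300 µM Cdc42) is pre-equilibrated between
its two forms at the clamped partner concentration, removing the fast
transient; sensitivity to this choice is negligible for the sweep ranges
used, because the binding reactions are much faster than the loss rates
everywhere except near zero partner.

The QSSA closed forms,
$T_{1/2} = \ln 2\,(k_{4a}\,Cdc42T/(k_{1b}k_{4b}) + 1/k_{1b})$ for
Bem1–GEF and
$T_{1/2} = \ln 2\,(k_3\,BemGEF42/(k_{2b}k_{5b}) + 1/k_{5b})$ for Cdc42,
agree with the simulated half-times pointwise within 10% across the full
sweeps (0–450 µM GTP-Cdc42; 0–40 µM GEF), and to < 2% when the
binding/unbinding pair is scaled 100-fold into the deep QSSA regime. One
caveat is deliberate and documented: because $k_{4b}$ is *equal* to
$k_{1b}$ (not much larger), the extrapolated intercept of a straight line
fitted through the simulated sweep lands near
$\ln 2\,(k_{1b}+k_{4b})/(k_{1b}k_{4b})$, about twice the QSSA intercept
$\ln 2/k_{1b}$ — an offset of 0.07 s on half-times spanning 31 s. The
acceptance checks therefore test the intercept as the simulated dwell
time at zero partner (which equals $\ln 2/k_{1b}$ exactly), together with
the slope, linearity and pointwise QSSA agreement; asserting the
regression intercept against the QSSA value would fail for any faithful
simulation of these kinetics, not because of numerical error.

## Linear stability analysis

The torus dispersion relation and mode counting use the analytic
Jacobian at the homogeneous steady state; admissible modes are the
integer lattice $q = 2\pi(m, n)/L$ with degenerate symmetric modes
counted individually. The strongest cross-module check seeds a single
Fourier mode (along its leading eigenvector, amplitude $10^{-3}$ µM) on
the homogeneous state and measures its exponential growth in the full
nonlinear simulator: measured rates match the eigenvalues to well under
1% for the first three unstable modes of the abundance-corrected regime.

Because the published set is subcritical, the mode-count sweeps are
anchored at the paper's own comparison: scaling both conserved totals by
the volume-correction factor 5.86 (= 258 fL model cell / 44 fL real
cell) opens a wide unstable band (80 lattice modes at $D_m = 0.0025$,
$m_{max} = 12$), and slowing diffusion from 0.03 to 0.0025 µm²/s
monotonically enlarges the unstable set at fixed abundance. One
discovered subtlety, asserted as its own property test: abundance does
*not* act monotonically across the whole interval [1, 5.86] — the count
peaks near scale 2 and narrows again at higher abundance (an instability
window). The corrected-versus-uncorrected comparison and the
(slow-diffusion, corrected-abundance) corner being maximal hold as
stated.

The sphere machinery is generic: a kinetics description (membrane
Jacobian, cytosol-surface coupling, adsorption-flux derivatives, per-
species cytosolic diffusion coefficients) defines, per spherical-harmonic
degree $l$, a characteristic equation obtained by matching the radial
cytosolic solution — modified spherical Bessel functions of the first
kind, regular at the origin, continued to ordinary spherical Bessel
functions for decaying roots — to the membrane perturbation with lateral
diffusion eigenvalue $-l(l+1)D_m/R^2$. Real roots are located by
sign-scanning the determinant and refined by Brent's method; the
pure-decay closed form is reproduced to $10^{-6}$. The shipped instance
is this package's own model (effective shell thickness
$\delta = \eta R/3$; cytosolic diffusion is a required input since the
flat model treats the cytosol as well mixed, i.e. the $D_c \to \infty$
limit); external kinetics can be plugged in when their rate constants are
available, but no attempt is made to reproduce numbers whose parameters
live in another paper's supplement.

## Synthetic microscopy and quantification

The imaging module mirrors a spot-based quantification workflow:
two-threshold segmentation (cell mask, spot threshold, minimum-area
filter), greedy nearest-neighbour tracking with optional blink bridging,
background-corrected vicinity traces (background = mean in-cell intensity
one frame before first detection, falling back to the per-frame interior
median), coexistence times from per-frame spot counts, FLIP normalization
`(focus - background)/(neighbor - background)`, double-exponential FRAP
fitting reporting $\ln 2/k_{slow}$, and multi-cluster percentages with
Clopper–Pearson intervals. Tie-breaking and pixel-membership rules that
the workflow leaves open are fixed and documented: spots are linked in
descending intensity order (ties to the lowest track id), and a pixel
belongs to a circle when its center lies within the radius.

The synthetic-data generator emulates what those analyses assume:
diffraction-limited spots as isotropic Gaussians (s.d. ~2 px) on a
constant background with additive Gaussian noise, scripted birth/death,
paths, blinking and two-channel delays; FRAP traces with three pre-bleach
frames and 23 post-bleach acquisitions at adapted (quadratically spaced)
intervals, dense early to resolve the fast cytoplasmic component; FLIP
schedules with a neighbor-cell control for indirect bleaching. Every
generator is seed-deterministic and returns machine-readable ground
truth. What the generator does **not** emulate — Poisson photon
statistics (optional flag aside), camera gain, z-structure, moving cells,
spatially varying background — bounds what the recovery tests show: they
validate the estimators against their own assumptions, not microscope
physics. The FRAP fitter is multi-start (the likelihood surface has
single-exponential ridges); with uniformly sampled traces whose fast
component ends before the second frame the slow rate is still recovered,
but the degenerate-fit fallback triggers more often — the adapted
schedule is the supported design, as it is in practice.

## Problem sizes and runtimes

Default analyses run at N = 64 (the peak diameter spans ~8 grid cells;
refinement checks use N = 48–96 and N = 128 for flux oracles).
Competition runs resolve in 600–900 s of simulated time per seed; the
test suite uses 10 seeds for outcome statistics plus 10 short
symmetry-breaking runs for the winner-side tally, and the acceptance
script uses 4 seeds. FRAP recovery statistics use 20 replicates per rate
constant, 5 rate constants. These sizes were chosen so the full analysis
reproduces on a laptop-class single core in well under an hour.

## Known limitations

* The torus geometry has no curvature or cell-shape coupling; the sphere
  appears only in the linear analysis.
* The noise term's spatial discretization ($s\,\mathcal N(0,1)/\sqrt{dt\,h^2}$
  per grid point, Euler–Maruyama) is a modelling choice the continuum
  description leaves open; quantities that depend on the noise amplitude
  (e.g. absolute coexistence times) are therefore reported but only
  order-of-magnitude meaningful, and all acceptance checks on noisy runs
  are structural (who wins, what balances, what is conserved).
* The negative-feedback model variant, explicit GAP/GDI species, 3D or
  deforming geometries, and particle-based simulation are out of scope.
* The cortical/interior intensity ratio is a deliberately simple
  mask-based approximation, not a calibrated cortical index.
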