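---
title: "Modelling interictal resting-state dynamics with a hybrid Epileptor–Hopf network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interictal resting-state dynamics with a hybrid Epileptor–Hopf network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Between seizures, the brain of a person with epilepsy mostly looks
"normal": resting-state networks, alpha-band oscillations, occasional
interictal spikes. This package simulates that interictal resting state at
the whole-brain scale. Each region of a structural connectome is a hybrid
neural mass with two subpopulations:

* an **Epileptor** subpopulation — the six-variable phenomenological model
  of seizure dynamics (`x1, y1, z, x2, y2, g`). The fast pair `(x1, y1)`
  generates ictal discharges, the second pair `(x2, y2)` generates
  spike-and-wave events, `g` low-pass filters `x1`, and the slow
  permittivity variable `z` (time constant `tau0 = 28571` ms) switches the
  node between interictal and ictal phases. The regional epileptogenicity
  `x0` controls this subsystem: above a critical value near **-2.05** the
  node seizes autonomously; just below it, noise triggers isolated
  interictal spikes; far below it the subsystem is silent.
* a **supercritical-Hopf oscillator** pair `(x3, y3)` representing healthy
  resting activity. Its drift is `dx3 = d(y3 - x3^3 + 3x3^2)`,
  `dy3 = d(a - 10x3 - y3)` with rate `d = 0.02`/ms, which places the Hopf
  bifurcation at `a_critic = 1.7402` (the trace of the Jacobian at the
  fixed point vanishes there) and gives the limit cycle a natural
  frequency of about 9.5 Hz — the dominant alpha rhythm of resting
  electrographic recordings. Below `a_critic` the node shows damped,
  noise-driven oscillation; above it, self-sustained rhythms.

The observable output of region *i* mixes the two ensembles through the
ratio `p_i`:

```
u_i = p_i (x2_i - x1_i) + (1 - p_i) x3_i
```

`x2 - x1` is the canonical Epileptor field-potential proxy; `p` close to 1
makes the epileptiform activity dominate (spiking or seizing regions), `p`
= 0.1 leaves the output essentially physiological.

Regions interact through two pathways on the normalised structural matrix
`C` (symmetric, non-negative, zero diagonal, unit maximum):
**permittivity coupling** `K_s * sum_j C_ij (x1_j - x1_i)` entering the
slow `z` equation (so that a seizing neighbour lowers `z` and recruits the
region; `K_s` is fixed at 0.1), and **fast diffusive coupling**
`K_rs * sum_j C_ij (x3_j - x3_i)` entering the Hopf equation (`K_rs` is
the free global coupling swept during fitting). Transmission is treated as
instantaneous; axonal delays are deliberately out of scope.

## Integration and noise

The network SDE is integrated with a stochastic Heun scheme at
`dt = 0.1` ms. Additive white Gaussian noise enters `x2` and `y2`
(strength 0.00025) and `x3` (strength 0.02); a strength `D` is interpreted
as a diffusion coefficient, i.e. each step adds an increment of standard
deviation `sqrt(2 D dt)`, applied identically in the predictor and the
corrected state. Each node draws its noise and its initial conditions from
its own counter-based random stream derived from `(seed, node index)`.
This makes runs bit-for-bit reproducible and gives an exact decoupled
limit: with `C = 0` a node inside the network reproduces the isolated
simulation of that node sample for sample (a property the test suite
asserts).

Initial conditions are a normal draw centred on the interictal rest state
`(-1.6, -12, 3, -1, 0, -0.16, 0, 0)`. The spread is 1 for the benign
variables but tightened to 0.25 on `x1` and `x2` and 0.1 on `z`: the
piecewise-cubic right-hand sides are numerically explosive at
`dt = 0.1` ms when started a few units outside their basins, and a `z`
started far below 3 puts the fast subsystem in a pathologically stiff
burst regime. The first 20 s of every run are discarded, so this choice
only affects the transient. Trajectories are stored decimated (every 10th
step, i.e. 1 ms resolution) as a memory contract for 20-minute runs.
Divergence (any |state| above 1e6) raises an error naming the node and
time; sweep drivers record such cells as failed and continue.

## From neural activity to fMRI-like BOLD

The mixed output drives the Balloon–Windkessel haemodynamic model (four
states per region: vasodilatory signal, inflow, venous volume,
deoxyhaemoglobin) with the standard Friston constants, frozen in
`hemodynamic_parameters()`: `kappa = 0.65`/s, `gamma = 0.41`/s,
`tau = 0.98` s, `alpha = 0.32`, `rho = 0.34`, `V0 = 0.02`, and observation
weights `k1 = 7 rho`, `k2 = 2`, `k3 = 2 rho - 0.2`. The neural drive is
demeaned per region and scaled by a gain (default 0.1) so the flow states
stay in their physiological regime; BOLD is reported in percent.

Post-processing reproduces empirical resting-state fMRI conditions: an
anti-alias low-pass followed by decimation to TR = 3.6 s (the downsampled
series has `floor(duration / TR)` volumes), regression of the global mean
signal out of each region, and a zero-phase third-order Butterworth
band-pass of 0.01–0.1 Hz. Regression precedes filtering, matching the
usual pipeline order; both steps can be toggled, because the empirical
comparison target is not always global-regressed (see the recovery
experiment below). Zero-phase filtering avoids phase distortion in the
Hilbert phases used downstream.

## The five observables and the Global Similarity score

For a BOLD series the package computes: the static Pearson correlation
matrix (sPCC); the functional-connectivity-dynamics matrix (FCD) from
60-s windows advancing one TR (window length `ceiling(60 / TR)` = 17
samples, so a 344-volume series yields exactly 328 windows); the Kuramoto
order parameter of the regional Hilbert phases, summarised as coherence
(time mean) and metastability (time SD); and the multiscale-entropy
profile — sample entropy (`m = 1`, tolerance `r = 0.35` SD, Chebyshev
distance, self-matches excluded) of coarse-grained series at scales 1–13
(3.6–46.8 s). Two conventions worth noting: the SampEn tolerance is fixed
from the SD of the original scale-1 series across all scales (the
canonical multiscale convention), and the Hilbert phases are computed on
demeaned series with the first and last 5% of samples trimmed against
transform edge effects. A constant series has no defined tolerance and is
flagged degenerate rather than crashed on.

Two simulations (or a simulation and an empirical reference) are compared
with five numbers: `corr` (Pearson correlation of the sPCC
upper-triangles), `ks` (Kolmogorov–Smirnov distance of the FCD
upper-triangle distributions), `|dCoh|`, `|dMeta|`, and the RMSD of the
MSE profiles. The composite Global Similarity score is

```
GS_raw = |dCoh| + |dMeta| + (1 - corr) + KS + RMSD^2
```

min–max normalised over a sweep to [1, 2]; the optimum is the argmin. The
quadratic RMSD term gives the complexity profile extra weight. The
normalisation preserves the raw-score ranking, so the argmin is invariant
to it.

## Scenarios and experiments

`build_epi_map()` translates a clinical zone assignment (epileptogenic
zone/primary irritative zone, propagation zone/secondary irritative zone,
non-involved zone) into per-region parameters:

| scenario | p (EZ / PZ / NIZ) | x0 (EZ / PZ / NIZ) | a |
|---|---|---|---|
| spike_free | 0.1 everywhere | -2.5 everywhere | homogeneous, caller-set |
| spiking | 0.9 / 0.7 / 0.1 | -2.07 / -2.25 / -2.55 | 1.74 |
| hyperexcitable | 0.1 everywhere | -2.5 everywhere | supercritical in EZ+PZ, 1.74 in NIZ |

The spiking x0 defaults sit at, 0.2 below, and 0.5 below the seizure
threshold of -2.05. The NIZ mixing ratio in the spiking scenario is not
pinned down by the zone definitions; we adopt the spike-free value 0.1 and
expose it as an override. Two spike-free x0 conventions circulate (-2.5
and "at least 0.5 below threshold", i.e. -2.55); the package defaults to
-2.5 and lets `x0_zone` override it.

Three scripted experiments mirror the in-silico studies this model was
built for: `working_point_sweep()` fits `(a, K_rs)` against a reference
BOLD by GS argmin; `spiking_sweep()` turns one region at a time into a
spiking focus and quantifies the change against a seed-matched spike-free
control; `hyperexcitability_sweep()` raises one region's `a` above
critical and does the same. Condition and control always share the RNG
seed, so differences reflect the manipulation, not the noise realisation.
Regional connectivity changes are tested with a two-tailed Wilcoxon
rank-sum z (normal approximation with tie correction; significance at
p < 0.05, equivalently |z| > 1.96); with fewer than two values per sample
— e.g. a two-region involved zone — the comparison is refused, mirroring
the clinical caveat.

## The synthetic connectome

`synthetic_connectome()` emulates streamline-count matrices: symmetric,
zero-diagonal, dense, log-normal (heavy-tailed) weights normalised to unit
maximum, seed-reproducible. It reproduces the *structural statistics* of
tractography, not the spatial organisation of a real brain: no
hemispheric blocks, no distance dependence, no hubs beyond what the heavy
tail produces. Tests passing on such toys show the machinery is correct
and the qualitative mechanisms (coupling raises coherence, a spiking
focus decouples) are present; they do not certify fits to real patient
data, for which the 84-region Desikan–Killiany parcellation reader and
zone tables are provided.

## Numerical choices and study sizes

Bisection for the critical points runs noise-free from the computed
interictal fixed point (a multivariate root of the drift) with a small
perturbation, because both critical values are deterministic properties.
For `a`, oscillation is called sustained when the late-window Hopf
amplitude neither collapses (above 1e-4) nor keeps decaying (at least 80%
of the preceding window); for `x0`, a seizure is an excursion of `x1`
above zero within 150 s. Both scans resolve the transition to 0.01,
within 0.02 of the published values, in under a minute each.

The packaged experiments run at desk scale: networks of 8 regions and, for
anything that feeds the BOLD observables, the full 20-minute scan length
(1200 s after discard). That duration is not negotiable downward: the
cross-seed reproducibility of a toy network's sPCC pattern is essentially
zero at 300 s (83 volumes) and only reaches ~0.4–0.7 at 1200 s, so
shorter runs measure nothing but noise realisation. This mirrors the
length of the empirical scans the observables were designed for.

## Parameter identifiability: what the recovery experiment can and cannot do

The working-point recovery experiment generates a pseudo-empirical
reference at known `(a, K_rs)` and asks the GS argmin over a 5×5 grid to
find it. Our analysis of this model shows a sharp asymmetry between the
two axes:

* **K_rs is identifiable.** Coupling raises the BOLD phase coherence
  strongly and monotonically (about 0.31 at `K_rs = 0`, 0.88 at 15, 0.93
  at 30 on the 8-node toy without global regression), and the sPCC
  pattern sharpens with it. The sweep recovers the generating `K_rs`
  exactly at the grid spacing used. Global-mean regression is disabled in
  this experiment: on a small, symmetric toy network it removes most of
  the shared variance that carries the coupling signal (cross-seed sPCC
  reproducibility roughly halves with it).
* **a is not identifiable from BOLD-band observables in this model.** The
  Hopf rhythm lives at ~9.5 Hz, two orders of magnitude above the
  0.01–0.1 Hz haemodynamic band. Linearly, the BOLD only sees the
  low-frequency content of the neural signal, which is dominated by the
  `x3` noise floor — and that floor is independent of `a`, because the
  envelope damping never approaches the carrier frequency anywhere in
  `a ∈ [1.0, 2.5]`. The `a`-dependent amplitude of the rhythm could reach
  the BOLD only through the weak second-order rectification of the
  Balloon model, which we measure at the percent level — far below the
  seed noise of the observables. Empirically, coherence, metastability,
  MSE and sPCC are flat in `a` from 1.0 to 2.5 (between-`a` differences
  smaller than within-`a` seed spread). The recovery test therefore
  documents this limit: the `K_rs` axis recovers within one grid step,
  the `a` axis does not, and the corresponding acceptance check is
  expected to fail on the `a` axis by construction, not by defect. The
  same analysis explains why raising one region's `a`
  (`hyperexcitability_sweep()`) leaves its BOLD connectivity essentially
  unchanged on a toy network (change of order 1e-4 against seed-matched
  control), whereas a spiking focus — whose discharges do have
  low-frequency power — decouples from the network robustly. Fitting `a`
  against *empirical* data, where all five observables differ from the
  model for many reasons, is a different and weaker claim than recovering
  it in a self-fit, and is outside what a toy network can demonstrate.

## Interfaces

All tabular results are tibbles (sweep cells, fit summaries,
classification, node strengths, zone maps) and chain with the pipe;
matrices (connectome, sPCC, FCD, MSE, BOLD) are labelled matrix classes
with `tidy()` and `autoplot()` methods. Files are plain text: CSV matrices
with label headers, JSON/YAML run configurations, JSON sidecars for BOLD
metadata; every writer/reader pair round-trips losslessly. The packaged
command-line front-end (`inst/cli/interictal.R`) covers the single-run
`simulate` use case; the sweep workflows are deliberately R-level
functions, which is where their inputs (references, grids, zone tables)
live naturally.

## Known limitations

Axonal delays, biophysical neuron models and regional heterogeneity of
the fixed constants are out of scope. The classifier thresholds
(high-pass 20 Hz, 6 robust SDs, 1 s gap closure, 2 s minimum ictal
duration, 3-MAD ictal dip) were designed against the model's own trace
morphology and validated on it; empirical electrographic data would need
re-tuning. The 84-label parcellation ships with best-effort abbreviations
where published tables are incomplete, and counts 35 cortical labels per
hemisphere by retaining the pericallosal label.
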