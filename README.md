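# interictal

Whole-brain network modelling of the **interictal resting state** in
epilepsy — the long stretches between seizures during which an epileptic
brain expresses resting-state networks, alpha rhythms and the occasional
interictal spike.

The package is for computational neuroscientists and epilepsy modellers
who want to simulate connectome-based brain network models of this state,
forward-model them to fMRI BOLD, and score them against resting-state
functional-connectivity (RS-FC) observables.

## The model

Each region *i* of a structural connectome `C` (symmetric streamline-count
weights, zero diagonal, normalised to unit maximum) is a hybrid neural
mass with two subpopulations:

* an **Epileptor** (variables `x1, y1, z, x2, y2, g`): fast ictal
  discharges, spike-and-wave events, and a slow permittivity variable `z`
  switching the node between interictal and ictal phases. Its
  epileptogenicity `x0` sets the regime: autonomous seizures above
  `x0_critic ≈ -2.05`, noise-triggered interictal spikes just below,
  silence far below. The parameter `b2` modulates spike frequency (lower
  `b2`, more spikes).
* a **supercritical-Hopf oscillator** (`x3, y3`) for healthy ~10 Hz
  resting activity, with bifurcation parameter `a`: damped noise-driven
  oscillation below `a_critic = 1.74`, self-sustained rhythm above.

The observable output mixes the two by a regional ratio `p`:

    u_i = p_i (x2_i − x1_i) + (1 − p_i) x3_i

Regions couple through a slow permittivity pathway
`K_s Σ_j C_ij (x1_j − x1_i)` (fixed `K_s = 0.1`) and a fast diffusive Hopf
pathway `K_rs Σ_j C_ij (x3_j − x3_i)` (the free global coupling).
Integration is stochastic Heun at `dt = 0.1` ms with additive white noise
on `x2, y2` (0.00025) and `x3` (0.02); every run is bit-for-bit
reproducible from its seed.

Simulated activity is transduced to BOLD by the Balloon–Windkessel model,
downsampled to TR 3.6 s, global-mean regressed and band-passed
0.01–0.1 Hz, then summarised by five RS-FC observables — static Pearson
correlation (sPCC), functional connectivity dynamics (FCD), Kuramoto
coherence and metastability, and multiscale sample entropy (MSE) — and by
a composite Global Similarity score

    GS_raw = |ΔCoh| + |ΔMeta| + (1 − corr) + KS + RMSD²,

min–max normalised to [1, 2] over a sweep; the model's working point is
the argmin.

## Worked example

```r
library(interictal)

# a streamline-count-like toy connectome, and a clinical zone assignment
conn <- synthetic_connectome(6, seed = 42)
zones <- tibble::tibble(region = rownames(conn),
                        zone = c("EZ_IZ1", "PZ_IZ2", rep("NIZ", 4)))
map <- build_epi_map(zones, "spiking")
map
#> # A tibble: 6 × 6
#>   region zone      x0     a     p    b2
#>   <chr>  <chr>  <dbl> <dbl> <dbl> <dbl>
#> 1 R1     EZ_IZ1 -2.07  1.74   0.9     4
#> 2 R2     PZ_IZ2 -2.25  1.74   0.7     4
#> 3 R3     NIZ    -2.55  1.74   0.1     4
#> # ...

traj <- simulate_network(conn, map,
                         coupling_parameters(k_s = 0.1, k_rs = 20),
                         integration_config(duration = 320, seed = 1))
classify_trace(traj$output[, "R1"], traj$dt)
#> # A tibble: 1 × 5
#>   class   spike_rate n_spikes n_seizures ictal_s
#>   <chr>        <dbl>    <int>      <int>   <dbl>
#> 1 spiking        0.4        2          0       0

bold <- neural_to_bold(traj)   # Balloon-Windkessel + TR 3.6 s + 0.01-0.1 Hz
round(unclass(static_pcc(bold))[1:4, 1:4], 2)
#>       R1    R2    R3    R4
#> R1  1.00 -0.41 -0.41 -0.69
#> R2 -0.41  1.00 -0.13  0.21
#> R3 -0.41 -0.13  1.00  0.00
#> R4 -0.69  0.21  0.00  1.00
coherence_metastability(kuramoto_order(instantaneous_phase(bold)))
#> # A tibble: 1 × 2
#>   coherence metastability
#>       <dbl>         <dbl>
#> 1     0.205         0.111
```

The epileptogenic region `R1` (`p = 0.9`, `x0 = -2.07`, just below the
seizure threshold) produced two interictal spikes in five minutes and no
seizure; the sPCC matrix shows the anti-correlations typical of
global-mean-regressed BOLD, and the network sits in a weakly synchronised,
metastable regime.

Sweeps return tidy tibbles: `working_point_sweep()` fits `(a, K_rs)`
against a reference BOLD via the GS argmin (see `plot_gs_landscape()`),
`spiking_sweep()` and `hyperexcitability_sweep()` perturb one region at a
time against a seed-matched control, and `compare_connectivity()` applies
the two-tailed rank-sum z-test (significance at |z| > 1.96).

## Package layout

* `connectome.R`, `io.R` — connectome and zone readers/writers, the
  synthetic connectome generator, the Desikan–Killiany label table,
  config serialisation.
* `node.R`, `simulate.R`, `classify.R` — node model, coupling, stochastic
  Heun integration (C++ core under `src/`), trace classification,
  bisection for the critical points.
* `hemo.R` — Balloon–Windkessel forward model and fMRI-like
  post-processing.
* `metrics.R` — the five RS-FC observables and the Global Similarity
  score.
* `experiments.R` — epileptogenicity maps and the three scripted sweep
  experiments with rank-sum statistics.
* `vignettes/interictal-methods.Rmd` — the model, its assumptions,
  numerical choices, and an identifiability analysis of the fitting
  problem.
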