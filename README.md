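# topolimit

Morphogen gradients — the spatial concentration profiles of secreted
signaling molecules like Sonic Hedgehog (SHH) — are classically modeled as
diffusion through a smooth continuum in which molecules alternate between a
bound (slow) and a free (fast) state. Under that *hindered diffusion*
picture the effective diffusion coefficient is fixed by the equilibrium
occupancies alone,

> D_eff = K_eq · D_free + (1 − K_eq) · D_con,

and the rate at which molecules interconvert is irrelevant. Single-molecule
imaging of SHH contradicts this: a catalyst (SCUBE1) that widens SHH
gradients accelerates the *exchange* between diffusive states without
changing their occupancies. `topolimit` implements the model that resolves
the contradiction — **topology-limited diffusion** — in which a tissue is a
lattice of discrete cells whose borders reflect membrane-confined
molecules, so long-range transport requires transitioning to the free
state, hopping the barrier, and rebinding. Under those rules the transition
rate (at fixed K_eq) and the cell–cell connectivity of the tissue both
control D_eff and the effective secretion flux J_eff.

The package is aimed at quantitative biologists who want to simulate the
model, and at single-particle-tracking (SPT) practitioners who want the
accompanying inference pipeline on trajectory tables:

* **Agent-based simulator** (`sim_params()`, `run_msd_protocol()`,
  `run_flux_protocol()`, `sweep_transition_scale()`): two-population
  Brownian agents on square-cell monolayers and stacked / half-offset
  bilayers, classic vs topology rules, D_eff via the MSD-slope/4 estimator
  and J_eff via a constant-occupancy source cell, with common random
  numbers across modes and scales.
* **Synthetic SPT generator** (`default_shh_state_model()`,
  `simulate_tracks()`, `scale_transition_rates()`): K-state
  Markov-switching Brownian tracks with localization error, truncated track
  lengths, and a catalysis knob that divides every state lifetime by *f*
  while provably preserving occupancies.
* **SPT inference** (`diffusion_histograms()`, `fit_state_hmm()`,
  `jackknife_intervals()`, `transition_trend_test()`,
  `normalize_bleach_trace()`): windowed maximum-likelihood diffusion
  spectra on a log D grid with localization-error marginalization, a
  4-state displacement hidden Markov model with lifetimes and delete-10%
  jackknife intervals, Bonferroni-corrected transition trend tests, and
  bleach-step counting.
* **Gradient quantification** (`radial_particle_counts()`,
  `smooth_profile()`, `meta_gradient()`, `fit_exponential_gradient()`):
  3 µm radial binning from the sender membrane, 9 µm smoothing, per-bin
  meta-gradients with SEM, and amplitude/lengthscale fits
  `A·exp(−x/λ) + b` with a model-free half-decay distance.

## Worked example

The defining contrast — the transition scale moves D_eff only under
topology rules:

```r
library(topolimit)
base <- sim_params(n_agents = 2000L, n_steps = 8000L, seed = 42L)
tab <- sweep_transition_scale(base, scales = c(0.1, 1, 10),
                              modes = c("classic", "topology"))
tab[, c("scale", "mode", "estimate", "se")]
#>   scale     mode estimate      se
#> 1   0.1  classic    0.536 0.02486
#> 2   0.1 topology    0.138 0.00859
#> 3   1.0  classic    0.538 0.02500
#> 4   1.0 topology    0.305 0.01251
#> 5  10.0  classic    0.542 0.02490
#> 6  10.0 topology    0.437 0.02029
```

Classic-mode D_eff sits at the occupancy-weighted mean
0.05·1 + 0.95·0.5 = 0.525 µm²/s at every scale (within Monte-Carlo error),
while topology-mode D_eff climbs from near the confined floor
(K_eq·D_free = 0.05) toward the classic value as switching accelerates —
one biochemical parameter tunes transport without touching occupancies.

Recovering the four SHH diffusive states from synthetic tracks:

```r
model <- default_shh_state_model()   # D = 20, 1, 0.2, 0.05 um2/s
tracks <- simulate_tracks(model, acquisition_spec(n_tracks = 2000L,
                                                  mean_track_len_frames = 20),
                          seed = 7L)
fit_state_hmm(tracks, K = 4L, seed = 1L)
#> <hmm_fit> K=4 on 2000 tracks (37754 displacements), sigma=0.028 um, logLik=59923.1
#>       D_um2s  occupancy lifetime_s
#>  20.38065149 0.09203341 0.03383857
#>   1.06313807 0.40295124 0.06382009
#>   0.25038879 0.35712421 0.05815007
#>   0.07727772 0.14789114 0.03807614
```

The two well-separated states (20 and 1 µm²/s) come back within a few
percent; the two slowest states sit inside the localization-noise floor of
one another and are recovered reliably as a pair (see the vignette for why
that is a property of the data, not the fitter).

A YAML-configured pipeline (`parse_config()` / `run_pipeline()`, or the
`inst/exec/topolimit` wrapper) runs the same stages end to end and writes
seed- and hash-stamped tables plus a manifest.

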