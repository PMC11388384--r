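---
title: "Topology-limited diffusion: models, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-limited diffusion: models, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topolimit)
```

## The model

Secreted morphogens such as Sonic Hedgehog (SHH) form concentration
gradients across fields of cells. Single-molecule tracking shows that such a
molecule does not diffuse as one homogeneous species: it alternates between
a fast, freely diffusing state and slower states associated with cell
membranes and matrix. Two pictures of what this means for transport can be
contrasted:

* **Classic hindered diffusion.** Space is smooth and continuous. The
  molecule alternates between a bound state with coefficient $D_{con}$ and a
  free state with coefficient $D_{free}$; with a free fraction $K_{eq}$ the
  effective coefficient is the occupancy-weighted mean
  $D_{eff} = K_{eq} D_{free} + (1 - K_{eq}) D_{con}$, independent of how
  fast the two states interconvert.

* **Topology-limited diffusion.** The tissue is a lattice of discrete cells
  whose borders are reflective barriers for the membrane-associated state.
  A confined molecule, however fast it moves *within* its cell, makes no
  long-range progress until it transitions to the free state, hops to a
  neighboring cell, and rebinds. Long-range transport is then rate-limited
  by the transition kinetics: scaling both transition probabilities together
  — leaving $K_{eq}$ untouched — changes $D_{eff}$, and the connectivity of
  the cell–cell contact network (the "tissue topology") matters.

The simulator in this package implements both rules over the same
agent-based core so they can be compared with common random numbers. Each
agent carries a position, a state (free / constrained) and, when
constrained, a home cell; one step of length $\Delta t$ applies the state
transitions and then a Gaussian displacement with per-axis variance
$2 D \Delta t$. In topology mode, constrained agents are folded back into
their home cell by exact specular reflection; in classic mode nobody sees a
barrier. The defaults follow the two-population parameter set used for the
model predictions: $\Delta t = 6$ ms, $D_{con} = 0.5$ and $D_{free} = 1$
µm²/s, $K_{eq} = 0.05$, 5 µm square cells.

### Lattice geometries

Three arrangements are supported: a `monolayer` (each interior cell has 4
edge-sharing neighbors), a `stacked_bilayer` (two coincident layers; 4
in-plane neighbors plus the 1 coincident cell, degree 5) and an
`offset_bilayer` (the second layer shifted by half a cell edge on both
axes; 4 in-plane plus 4 quarter-overlapping cells, degree 8). "Neighbor"
means nonzero overlap area — the four corner-touching cells of the offset
arrangement have zero overlap and are excluded. A bilayer stands in for a
thin three-dimensional interface between two cell layers: a molecule that
rebinds chooses the upper or lower layer with equal probability.

```{r degrees}
sapply(c("monolayer", "stacked_bilayer", "offset_bilayer"), function(a)
  length(neighbor_cells(cell_id(0, 0, 0), lattice_spec(arrangement = a))))
```

### Transition parametrization

The headline comparison varies the transition rate *at fixed equilibrium
occupancy*, so the package parameterizes the per-step probabilities as
$p_{c \to f} = s\,p_0$ and $p_{f \to c} = s\,p_0 (1 - K_{eq})/K_{eq}$,
where $s$ is `switch_scale`: the stationary free fraction is exactly
$K_{eq}$ at every $s$. A literal 20-fold rate asymmetry (stationary free
fraction $1/21 \approx 4.8\%$) is available via `ratio20 = TRUE`; the two
conventions agree to about 5% and both are exposed rather than silently
merged. The default base rate $p_0 = 0.005$ per 6 ms step gives a
constrained-state lifetime of 1.2 s at $s = 1$, so the interesting regime —
confinement felt at small $s$, barriers barely felt at large $s$ — falls
inside a 100× scale range. At small $K_{eq}$ the free-to-constrained
probability grows as $(1-K_{eq})/K_{eq}$; sweeps choose $p_0$ so that the
scaled value stays a valid probability.

### Protocols

* `run_msd_protocol()` starts all agents uniformly in one sender cell (a
  fraction $K_{eq}$ free) and records the mean squared displacement from
  the cell center; `estimate_deff()` fits the slope over the final half of
  the curve (configurable) and divides by 4, the two-dimensional relation
  $\mathrm{MSD}(t) = 4Dt$. Defaults are 5,000 agents and 20,000 steps
  (120 s simulated). The Monte-Carlo standard error is a bootstrap over 50
  independent agent groups.
* `run_flux_protocol()` holds the sender cell at a constant occupancy
  (default 2,000 molecules, topped up every step); molecules that leave
  join the receiver field and keep diffusing, molecules that re-enter the
  sender are removed. $J_{eff}$ is the steady-state slope of the field
  count versus time (default 40,000 steps, 240 s).
* `sweep_transition_scale()` runs either protocol over a grid of
  `switch_scale` values, reusing the seed across modes and scales. Because
  every agent consumes the same number of random draws per step regardless
  of parameters, runs at different scales share aligned random-number
  streams; mode and scale contrasts are therefore paired and far more
  precise than independent runs of the same size.

Order within a step is transitions first, then movement (a newly freed
agent moves at $D_{free}$ immediately); a molecule that rebinds takes its
home cell from its current position. The lattice is sized (default ±200
cells) so agents essentially never reach the boundary; an agent that does
raises an error rather than wrapping, since the model assumes an unbounded
field.

## Synthetic single-particle tracking

`simulate_tracks()` generates the observable that single-molecule TIRF
imaging of a labeled morphogen produces: short two-dimensional tracks of a
molecule switching among $K$ Brownian states. Hidden states follow a
per-frame Markov chain (at most one transition per frame interval), true
displacements are Gaussian with per-axis variance $2 D_k \Delta t$, and
observed positions add independent localization error
$\mathcal{N}(0, \sigma^2)$ per axis. Track lengths are truncated-geometric
on 3–100 detections. Hidden states are kept alongside the observations so
every inference test is a parameter-recovery test.

`default_shh_state_model()` encodes the four observed diffusive regimes —
roughly 20 (free extracellular), 1 (cholesterol-anchored membrane
diffusion), 0.2 (receptor/membrane-protein bound) and below 0.1 µm²/s
(matrix-associated; represented as 0.05). The published occupancies and
pairwise rates are graphical only, so the defaults — occupancies
(0.10, 0.40, 0.30, 0.20), lifetimes of 30–60 ms — are explicit,
overridable placeholders and are never used as recovery truth; tests plant
their own values. `scale_transition_rates(model, f)` multiplies every
off-diagonal entry of the transition matrix by $f$: stationary occupancies
are exactly preserved ($\pi(I + f(A - I)) = \pi$ whenever $\pi A = \pi$)
while every lifetime divides by $f$ — the signature of a transition
catalyst such as SCUBE1.

What the generator deliberately does **not** emulate: motion blur (the
slow-acquisition regime it mimics used stroboscopic excitation precisely to
suppress blur), defocalization of fast molecules out of the ~100 nm
evanescent field (available only as an optional state-dependent
track-length bias, since the simulation is two-dimensional), spot
detection/linking errors, and photophysics beyond track termination.
Passing recovery tests on these tracks therefore shows the estimators are
correct under the stated model, not that real detection biases are absent;
the known consequence — transitions into and out of the fastest state are
under-observed because fast molecules leave the focal volume — must be kept
in mind when reading fitted transition matrices.

## Windowed diffusion spectra

`window_mle_diffusion()` evaluates, for a window of $n$ frame intervals
with summed squared displacement $S = \sum (\Delta x^2 + \Delta y^2)$, the
likelihood under per-axis variance $v = 2 D \Delta t + 2\sigma^2$ on a
log-spaced grid of $D$ (default 0.01–100 µm²/s, 101 points) crossed with a
linear grid of $\sigma$ (default 0.025–0.05 µm); $\sigma$ is marginalized
with a uniform prior and the grid argmax over $D$ is returned. $(n, S)$ are
sufficient, which keeps the rolling decomposition of thousands of tracks
(`diffusion_histograms()`) cheap. Windows of 3 intervals (18 ms at 6 ms
frames) approximate pure states; in longer windows, molecules that switch
state inside the window surface as spurious intermediate coefficients —
the growth of that intermediate mass with window length, and its shift to
shorter windows when rates are catalyzed, is the fingerprint used to read
transition kinetics off the spectra. Histograms use 60 bins in
$\log_{10} D$ over the grid range; any log-scaling of densities is left to
plotting.

## The displacement hidden Markov model

`fit_state_hmm()` runs expectation–maximization over per-interval
displacement emissions: state $k$ emits per-axis Gaussian displacements
with variance $2 D_k \Delta t + 2\sigma^2$, and the chain moves once per
frame at most. The forward–backward pass is exact (compiled, scaled);
the M-step updates per-state variances, the transition matrix and the
initial distribution. Reported occupancies are posterior time fractions.
States are canonicalized by descending $D$; lifetimes are the geometric
dwell means $\Delta t / (1 - A_{kk})$.

**Localization error.** With independent-displacement emissions a shared
$\sigma$ is not identifiable jointly with free per-state variances — it
trades off exactly against the slowest $D$. The package instead uses the
moment identity $\mathrm{Cov}(\Delta x_t, \Delta x_{t+1}) = -\sigma^2$,
which holds for Brownian motion plus static noise regardless of the hidden
state, to estimate $\sigma$ from the pooled lag-1 displacement
autocovariance (`estimate_loc_error()`), clamps it to the instrument band
(0.025–0.05 µm) and holds it fixed during EM. The emission model ignores
the $-\sigma^2$ covariance this same effect induces between successive
displacements; this matches the independent-window approximation of the
spectral method and costs a little efficiency, not consistency of the
marginal variances.

**Initialization and restarts.** EM is started from $K$ quantiles of the
3-interval windowed-MLE distribution, plus jittered restarts (default 5);
the best likelihood is kept and non-convergence is flagged on the result,
never silent.

**Known limitation.** States separated by less than the noise floor
($2\sigma^2 \approx 0.0025$ µm², i.e. $D \lesssim 0.2$ µm²/s at 6 ms)
exchange probability mass between fits: the 0.2 and 0.05 µm²/s states are
recovered as a pair much more reliably than individually, and
transition-matrix-implied occupancies can deviate from instantaneous
occupancies. The well-separated states (20 and 1 µm²/s) are recovered to
within a few percent with ~2,000 tracks.

`jackknife_intervals()` repeats a fit on 10 subsamples each omitting a
disjoint 10% of tracks (folds assigned deterministically from the seed) and
reports per-parameter replicate spread, with replicates aligned by the
descending-$D$ ordering. `transition_trend_test()` correlates each of the
$K(K-1)$ off-diagonal transition probabilities against a condition level
(Pearson), at the Bonferroni-corrected per-test threshold
$\alpha / (K(K-1))$ — $0.05/12 = 0.00417$ for four states — and reports the
high-versus-low fold change; constant inputs give an undefined correlation
reported as not significant.

`normalize_bleach_trace()` rescales an intensity trace to pre-bleach mean 1
and post-bleach mean 0 and smooths over 3 frames for display; step counting
runs a binary-segmentation change-point scan on the *unsmoothed* normalized
trace (the rolling mean would turn each step into a ramp of its own
levels), with a BIC-style penalty and a minimum accepted drop of 0.2.

## Gradient quantification

`radial_particle_counts()` histograms particle distances measured from the
sender cell *membrane* (not centroid) into contiguous 3 µm bins, keeping
raw counts; `smooth_profile()` applies a centered moving average over a
9 µm span (shrinking at the edges); `meta_gradient()` averages profiles
over sender cells with per-bin SEM. `fit_exponential_gradient()` fits
$y = A e^{-x/\lambda} + b$ by Levenberg–Marquardt, initialized from a
log-linear regression — the exponential is the steady-state profile of the
synthesis–diffusion–degradation model, so it is the defensible default
form, but because a reported "lengthscale" need not be an exponential decay
constant the model-free half-decay distance is emitted alongside
$\lambda$. Noiseless exponentials are returned from the log-linear solution
directly (the least-squares gradient is singular at an exact optimum), flat
profiles are flagged `no_gradient`, and $\lambda$ is scale-invariant in the
counts while the amplitude scales linearly.

```{r gradient}
sets <- simulate_gradient_particles(amplitude = 80, lambda_um = 17,
                                    n_cells = 30, seed = 1)
profs <- lapply(sets, radial_particle_counts, max_um = 120)
meta <- meta_gradient(profs)
head(meta, 4)
```

## Reproducibility plumbing

`parse_config()` reads a YAML run configuration (stage, mandatory seed,
stage parameters; unknown keys rejected) and stamps it with a content hash;
`run_pipeline()` executes the stage, writing tab-separated tables whose
header comment records the seed and hash, plus a JSON manifest. Given the
same configuration and seed the tables are byte-identical. The
`inst/exec/topolimit` script is a thin command-line wrapper over these two
functions; the R functions are the primary interface.

## Problem sizes and numerical tolerances

The package's own test battery runs the effective-diffusion protocol at
1,500–5,000 agents and 6,000–20,000 steps, sweeps five transition scales
over a 100× range for five (occupancy, cell-size) combinations, compares
bilayer arrangements over ten paired replicates, and fits the four-state
HMM on 1,400–2,500 synthetic tracks — sizes chosen so Monte-Carlo error is
comfortably below the effects under test while a full run stays in the
minutes range on one core. Stochastic recoveries are asserted within 3
Monte-Carlo standard errors (simulation protocols) or 10–35% (HMM
parameters, reflecting the noise floor discussed above); exact identities
(connectivity degrees, dwell-time arithmetic, threshold constants) are
asserted exactly.

## Limitations

Continuum solutions of the gradient, receptor binding and degradation
kinetics, three-dimensional off-lattice simulation, raw image synthesis and
spot detection/linking are all out of scope; trajectory tables are consumed
as produced by upstream tracking software (a maximum linking distance of
1.71 µm is recorded as metadata, not enforced). The displacement HMM is a
deliberately simplified equivalent of published state-array and HMM
tools — shared scalar localization error, independent-displacement
emissions, plain per-frame chain — and where its behavior is known to
differ (slow-state mass exchange, occupancy conventions) that is stated
above rather than absorbed into defaults.
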