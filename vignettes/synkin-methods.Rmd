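---
title: "Models and methods in synkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in synkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synkin)
```

`synkin` implements three connected pieces of the computational machinery
used to study fast GABAergic synaptic transmission: a particle-based Monte
Carlo model of transmitter release and receptor activation in the synaptic
cleft, an analysis pipeline for inhibitory postsynaptic currents (IPSCs),
and an analysis pipeline for single-particle tracking (SPT) of membrane
receptors. A synthetic-data module generates inputs with known ground
truth for every analysis stage, so the whole pipeline is testable without
any experimental recordings. This vignette explains the models, their
assumptions, the tunable parameters, and the numerical choices.

## Receptor gating schemes

Receptor gating is modelled as a continuous-time Markov chain over a small
set of states, each flagged open or shut and carrying a count of bound
agonist molecules. Transition rate constants are either
concentration-independent (1/ms) or first-order in agonist concentration
(1/mM/ms); binding transitions must increase the bound count by exactly
one, which is what lets the particle simulator conserve agonist.

The true rate constants of the receptors the package is aimed at are not
published in a reusable form, so `synkin` ships two structural *templates*
with documented placeholder rates, every one of which is configurable:

* `scheme_biliganded()` — the classic sequential scheme
  `C <-> CA <-> CA2 <-> O` with a desensitized state `D` off the fully
  bound shut state. Openings require both binding sites occupied.
* `scheme_petrini()` — a structurally different scheme with a
  low-efficacy mono-liganded open state, cooperative binding (the second
  site binds faster than the first) and desensitization, so that
  model-dependence of simulation conclusions can be checked.

The placeholder rates were calibrated once, against the master-equation
solver and small pilot ensembles of the particle simulator, to reproduce
three qualitative behaviours expected of these receptors:

1. *Decay in the fast-IPSC range.* Open-state occupancy after a brief
   (sub-millisecond) millimolar agonist pulse decays with a
   mono-exponential time constant of roughly 13 ms (within the typical
   10–20 ms band).
2. *Decay is a per-receptor property.* Agonist unbinding is slow
   relative to the decay (`koff2 = 0.06` /ms): transmitter is held
   through gating and desensitization cycles, so the synaptic decay
   reflects each receptor's own relaxation rather than
   unbinding-and-rebinding within the cluster. This is what makes the
   simulated decay time constant insensitive to how densely the
   receptors are clustered — with faster unbinding, rebinding in dense
   clusters re-activates receptors and couples tau to cluster size,
   which is not what is observed for these synapses.
3. *Prolonged release slows the decay.* Desensitization equilibrates on
   a ~10 ms timescale, so receptors activated by a brief single-vesicle
   transient are still desensitizing when the current decays (extra
   decay rate), while a release phase stretched over 5 ms drives them
   closer to desensitization equilibrium by the time of the peak,
   visibly slowing the fitted decay.

The templates are stand-ins for data-derived schemes: absolute peak
counts and time constants from the defaults are *not* predictions, but
trends across geometry, diffusion and release-schedule changes are
meaningful, and that is what the test suite asserts.

Three engines propagate a scheme:

* `solve_master_equation()` — deterministic occupancy probabilities by
  exact matrix exponentials on each piecewise-constant concentration
  segment (`Matrix::expm`); no stiffness tuning, exact for the step
  profiles used. This is the well-mixed oracle.
* `simulate_gillespie_ensemble()` — exact stochastic simulation of an
  ensemble of independent channels, aggregated over state counts, with
  waiting times capped at concentration-segment boundaries.
* `simulate_channels_uniform()` — the discrete-time per-step update used
  by the cleft simulator's gating engine (leave probability
  `1 - exp(-R dt)`, rate-proportional branching), exposed under a uniform
  concentration so it can be validated against the oracle. Its
  discretization bias is second order in `rate * dt`; at the default
  `dt = 0.005` ms and template rates it is well below the Monte Carlo
  noise of a 10^4-channel ensemble.

`detailed_balance_check()` reports Kolmogorov-criterion violations on
cycles (report only — irreversible schemes are legitimate).

## The cleft simulator

`run_trial()` simulates a simplified synapse: a 1 × 1 × 0.5 μm presynaptic
bouton whose underside sits one cleft width (default 20 nm) above a large
postsynaptic plane; 300 receptors in a centred square cluster (default
side 200 nm); one vesicle = 3000 transmitter molecules appearing at a
point 1 nm below the bouton centre; transmitter diffusion coefficient
0.3 μm²/ms. Molecules take Gaussian steps, reflect off the postsynaptic
plane everywhere and off the bouton while laterally under its footprint,
diffuse freely beyond it, and are removed at an escape radius (default
5 μm) — the outer boundary is not part of the modelled physics, only a
cost bound, and the default radius is far enough that cleft dynamics are
unaffected on the simulated timescale.

**Binding microphysics.** Receptors are reactive disks of capture radius
5 nm on the plane. A molecule whose step carries it through the plane
within the capture radius of a receptor with a free site binds with the
probability returned by `calibrate_binding_probability()`,

$$p \;=\; \frac{k_{on}}{\nu\, r^2}\sqrt{\frac{dt}{\pi D}},$$

derived by equating the mass-action flux per receptor, `k_on * C`, with
the product of the Brownian one-way plane-crossing flux per area per step
(`n sqrt(D dt / pi)` for number density `n = ν C`) and the disk area
`π r²`. Both the calibration and the detector count *endpoint* crossings
(a step that starts above and ends below the plane), so the convention
cancels; `p` scales with `sqrt(dt)` while crossings per unit time scale
with `1/sqrt(dt)`, making the flux step-size invariant. The package
validates this directly (`validate_binding_calibration()`): in a closed
box the observed flux matches mass action to ~1% and is invariant under
halving `dt`. Ties (a crossing within reach of several receptors) go to
the nearest free receptor, then the lower index.

**Step-size policy.** The fine step must resolve the cleft:
`sqrt(4 D dt) < cleft/2` (enforced; the default
`dt = (0.45 cleft)²/(4D)` satisfies it with a 10% margin for every
swept diffusion coefficient and cleft width). That resolution is only
physically necessary inside the cleft slab, where the half-space
crossing-flux calibration would otherwise be biased, so steps are
banded: molecules within 50 nm of the plane *and* laterally under the
bouton footprint (plus a 0.1 μm approach margin) step at `dt`; elsewhere
molecules below 0.25 μm step at `10 dt`, below 2 μm at `100 dt`, and
beyond at `1000 dt`, each tier's binding probability re-calibrated for
its own step length (receptors outside the footprint, as on the largest
swept clusters, sit under open half-space where the calibrated coarse
step is valid). A molecule at a tier boundary is always ≥ 4 standard
deviations of the coarser step away from the plane; the free-diffusion
variance identity and the mass-action check above guard the stepping
machinery. Receptor gating (concentration-independent transitions) is
updated every five base ticks, keeping `rate * dt ≈ 0.01`; unbinding
re-injects the agonist just above the receptor. Everything is driven by
one counter-based RNG, so a trial is bit-reproducible from its seed.

**Outputs and summaries.** A trial reports open/bound/free/escaped counts
on a regular grid (molecule conservation is asserted in tests at every
sample) and optionally a per-receptor event log. `run_ensemble()` averages
the open-count trace over consecutive seeds (the convention for reporting
simulated synaptic currents); `summary()` on an ensemble reports the peak
of the averaged trace and a mono-exponential decay time constant
(`A e^{-t/τ} + C`) fitted over the full window from the peak to the end
of the trace. The window is deliberately fixed: data-dependent
truncation rules (such as cutting at the return to 10% of peak) were
found to dominate the variance of τ on noisy low-amplitude traces, while
the free offset stably absorbs the residual slow desensitization tail.
Event-level IPSC fitting keeps the conventional 10%-of-peak window. A
bi-exponential mode reporting the amplitude-weighted τ is available.
`parameter_sweep()` re-runs ensembles along one axis (cluster side,
diffusion coefficient, cleft width, or release schedule) and tabulates
peak and tau with seeds and a configuration hash per row.

Simulated problem sizes in the tests and the acceptance script — 300
receptors, 3000 molecules per vesicle, 50 ms of simulated time, 20 seeds
per ensemble (8–10 for the five-vesicle comparisons, whose trials carry
five times the molecules) — were chosen as the smallest ensembles that
give stable peak/tau estimates across the swept conditions.

## IPSC analysis

`detect_events()` implements sliding-template detection with the
scaled-template (Clements–Bekkers) criterion: at each offset the template
is optimally scaled and offset by least squares and the criterion is the
scale divided by its standard error. Detections are local maxima of the
criterion above threshold; detections closer than one template length are
merged keeping the larger criterion (the criterion stays elevated along
an event's decay tail, so shorter merge windows split events). The
default threshold is 3.5; for quantitative recovery checks the suite
uses 4, where the false-alarm rate on pure noise is of order one per 10^6
samples and the criterion of true events at signal-to-noise 5 is an order
of magnitude higher.

Event metrics follow the standard conventions: 10–90% rise times by
linear interpolation between the samples bracketing the thresholds;
decay time constants by Nelder–Mead simplex least squares on
`A exp(-t/τ) + C` (bi-exponential mode reports the amplitude-weighted
τ), fitted from the peak with the baseline estimated from 5 ms before
onset; `cell_summary()` averages *fitted parameters* across a cell's
events by default — averaging the waveform first and fitting once is an
explicit alternative mode, never silently mixed — and excludes fits with
R² < 0.5 (count reported). Rise and decay metrics are invariant under
amplitude scaling and baseline offsets.

Derived quantities: `q10()` computes the temperature coefficient
`(τ_cold/τ_warm)^(10/ΔT)` — values above ~2 implicate protein
conformational kinetics rather than aqueous diffusion;
`percent_of_control()` normalizes a drug-phase mean to the average of
pre-drug and wash phases to cancel run-down/run-up, falling back (with a
flag) to pre-drug alone; `rc_corner_frequency()` is `1/(2πRC)` in
recording units (MΩ, pF).

## Single-particle tracking analysis

Trajectories are tables of (track, frame, t, x, y) in μm and seconds,
origin at the image corner with y increasing downward so coordinates map
directly onto mask pixels; drift correction is assumed upstream.

`compute_msd()` is the time-averaged MSD using **all overlapping pairs**
per lag (the common convention; frame gaps are honoured by matching frame
differences exactly). It is tested for exact equality against a
brute-force all-pairs oracle. `mean_msd()` applies the ≥ 20-point track
filter — shorter tracks give individual-MSD estimates too noisy to use —
and averages per lag across tracks; per-cell diffusion coefficients come
from this mean curve, not from averaging per-track fits.

Two fits are offered. The linear model `MSD(t) = 4Dt + b` is fitted to
the first four lags; the intercept absorbs static localization noise
(`b ≈ 4σ²`, checked in the suite for σ = 40–60 nm). The confined model

$$MSD(t) = \frac{L^2}{3}\left(1 - e^{-12Dt/L^2}\right) + 4D_{mac}t$$

is fitted by Levenberg–Marquardt (`minpack.lm`) with non-negativity
bounds; `L` is the side of the confining domain (plateau `L²/3` when
`D_mac = 0`). Starting values come from the tail slope (for `D_mac`),
the initial slope (for `D`) and the implied plateau (for `L`);
non-convergence falls back to the linear fit with a flag. A fit is
flagged *unstable* when the confinement shoulder is not reached within
the fitted lags (`12 D t_max / L² < 1`) or the relative standard error
of `L` exceeds 50% — the expected behaviour on freely diffusing
particles.

"Instantaneous" diffusion coefficients (`instantaneous_D()`) are the
linear fit applied to each track's own MSD — the package's
interpretation, since the term has no unique definition. The population
histogram is over log₁₀D; bimodality is declared when a kernel density
of log₁₀D has two modes with the smaller at least 10% of the larger and
a valley dipping below 80% of the smaller mode, and the split point is
the valley (fixed fallback split 0.02 μm²/s otherwise).

`classify_by_mask()` labels a track synaptic when ≥ 80% of its
localizations fall in the presynaptic mask (dilated by one localization
precision, 50 nm, to absorb pointing error), extrasynaptic at ≤ 20%, and
exchanging otherwise; the thresholds are package choices — the source
experiments state the overlap only qualitatively.

`mobility_metrics()` reports the ensemble D, synaptic/extrasynaptic D
(with and without the exchanging tracks) and the mobile fraction. The
mobile fraction ("free diffusion or changing domains") is decided
hierarchically: per-track confinement fits on 20–50-point tracks
misclassify a large fraction of both free and confined tracks (the
long-lag points of a single-track MSD are means of very few pairs), so
single-track instability is not a usable mobility flag. Instead, when
the instantaneous-D distribution is bimodal the fast mode plus the
exchanging tracks are mobile; when it is unimodal the confined fit of
the *ensemble* mean MSD — which has the statistics to decide — labels
the whole population confined (mobile = exchangers only) or free (all
mobile).

`detect_clusters_and_distances()` is a density-based (DBSCAN-style)
clusterer with a grid-bucketed neighbour search (ε = 100 nm, 10 points
by default; the source experiments never name their method) reporting
centroids, sizes and nearest-neighbour centroid distances.

## Synthetic data

Every generator takes a mandatory seed, sandboxes R's RNG, and returns
the dataset together with a truth object carrying all generating
parameters, so analyses can be scored against ground truth and datasets
regenerated bit-identically.

* `gen_free_tracks()` — Brownian steps of per-axis variance `2D/fps`
  plus i.i.d. Gaussian localization noise per point. Track lengths are
  geometric (photobleaching-like) truncated below at 5 points by
  default, so the ≥ 20-point filter has realistic work to do; fixed
  lengths are available for calibration tests.
* `gen_confined_tracks()` — reflected Brownian motion in a square (or
  disk) of size `L` whose centre diffuses with `D_mac`; reflection (ten
  substeps per frame) rather than a harmonic potential, matching the
  square-domain model behind the `L²/3` plateau. The per-frame step must
  not exceed `L/2`.
* `gen_two_population_tracks()` — a slow confined population (optionally
  seeded inside mask puncta) plus a fast free population, with per-track
  truth labels; defaults (25× D contrast) produce the bimodal log-D
  histograms seen for clustered versus free membrane receptors.
* `gen_mask()` — binary disk puncta at given or Poisson-scattered
  centres (overlaps merge in the mask, centres retained in truth).
* `gen_ipsc_trace()` — difference-of-exponential events (template long
  enough that slow decays are not truncated) at Poisson times, negative
  going, plus white Gaussian noise; every event is in the truth table,
  overlaps permitted.

What the generators do *not* emulate: photophysics (blinking, conversion
efficiency), motion blur, camera noise, vesicle-release stochasticity
beyond Poisson timing, and correlated recording noise. Passing
round-trip tests therefore demonstrates estimator correctness on the
stated generative models, not robustness to every artefact of real
recordings.

## Reproducibility and I/O

All lengths are μm, times s (tracking) or ms (simulation and IPSC
kinetics), conversions at the boundary only. Readers and writers cover
tracking CSVs (malformed rows dropped and counted), TIFF masks, trace
CSVs and key–value scheme files (lossless round trip).
`write_results()` emits deterministic CSV/JSON plus a manifest (seed,
config, md5 checksums, package version) sufficient to reproduce outputs;
`expand_seeds()` maps one user seed to per-stage seeds (all below 2³¹)
by a fixed counter scheme. The package's functions, this vignette and
the scripts are the interface; no separate command-line wrapper is
shipped.

## Known limitations

* Template rates are placeholders: absolute peaks and taus from the
  default schemes are illustrative, trends are the supported output.
* The templates operate at higher receptor engagement (~40% of a 200 nm
  cluster per vesicle) than the receptors they stand in for. This keeps
  the decay fit well-conditioned even when 300 receptors are spread over
  a 1600 nm cluster, but it means a five-vesicle volley saturates the
  densest cluster, masking there the decay prolongation that prolonged
  release produces at larger cluster sides. Reducing the binding rates
  to an unsaturated regime restores the prolongation at every size but
  leaves too few open receptors at the largest cluster for a stable
  decay fit at 20 seeds. With data-derived rates (a cleanly
  mono-exponential deactivation) both behaviours should be observable at
  once; with these stand-ins, cluster-invariance of the decay was
  prioritized.
* The cleft simulator has no transporters or extracellular-matrix
  tortuosity; the bouton is a box; receptor geometry is a flat disk.
* Endpoint-crossing binding undercounts within-step round trips by
  construction; the calibration absorbs this consistently, but `p`
  values approaching 1 (very large `k_on` with coarse `dt`) would break
  the linearity and are rejected.
* Classification thresholds (80/20 residency, one-σ dilation) and the
  bimodality rule are fixed package choices; sensitivity to them is not
  explored automatically.
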