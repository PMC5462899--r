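# synkin

Tools for studying fast GABAergic synaptic transmission: a particle-based
Monte Carlo simulator of the synaptic cleft, an inhibitory postsynaptic
current (IPSC) analysis pipeline, a single-particle tracking (SPT)
analysis pipeline, and seed-deterministic synthetic-data generators with
ground truth for every stage.

The scientific question the package serves: when a receptor subtype
mediates slower synaptic currents, is that because its receptors are less
clustered at the synapse (so transmitter must diffuse to distant
receptors), or because the receptors gate differently? `synkin` provides
the computational side of that investigation — simulate what receptor
de-clustering, transmitter diffusion, cleft geometry and multi-vesicle
release do to the simulated current; quantify IPSC kinetics and their
temperature sensitivity (Q10) from recordings; and measure receptor
mobility, confinement and synaptic residency from tracking data.

## Models at the core

**Receptor gating** is a continuous-time Markov chain over states
`(label, open, n bound)` with transition rates that are constant (1/ms)
or first-order in agonist concentration (1/mM/ms). Two configurable
template schemes ship: a sequential bi-liganded scheme
`C ⇌ CA ⇌ CA₂ ⇌ O` with desensitization, and a scheme with mono-liganded
openings and cooperative binding. The master equation is solved exactly
by matrix exponentials on piecewise-constant concentration segments;
stochastic twins (exact Gillespie, and the per-step engine used inside
the particle simulator) are validated against it.

**The cleft simulator** releases vesicles of 3000 transmitter molecules
from a point source 1 nm under the centre of a 1 × 1 × 0.5 μm bouton
sitting 20 nm above the postsynaptic plane, diffuses them (D = 0.3
μm²/ms by default) with reflecting boundaries, and lets them bind 300
receptors clustered in a 200 nm square. Binding uses reactive capture
disks with a per-crossing probability calibrated so a well-mixed
simulation reproduces the mass-action flux `k_on · C · N`:

    p = k_on / (ν r²) · sqrt(dt / (π D)),   ν = 6.022e5 μm⁻³ mM⁻¹

**IPSC analysis**: sliding-template detection (Clements–Bekkers scaled
template criterion), 10–90% rise times, simplex mono/bi-exponential decay
fits `A·exp(-t/τ) + C`, per-cell averaging of fitted parameters,
`Q10 = (τ_cold/τ_warm)^(10/ΔT)`, drug effects as percent of the
pre/wash-averaged control, and the recording RC corner frequency
`1/(2πRC)`.

**SPT analysis**: time-averaged MSD (all overlapping pairs, exact against
a brute-force oracle), the linear fit `MSD(t) = 4Dt + b` on the first
four lags (b absorbs localization noise, ≈ 4σ²), the confined fit
`MSD(t) = L²/3 (1 − e^(−12Dt/L²)) + 4 D_mac t`, instantaneous-D
histograms with bimodality detection, classification of tracks against
presynaptic masks (synaptic / extrasynaptic / exchanging), mobility
reports and density-based cluster spacing.

## A worked example

Simulate a synapse at two clustering densities and fit the simulated
currents, then compute the temperature coefficient from measured decay
constants:

```r
library(synkin)

ens <- run_ensemble(sim_config(seed = 1), n_seeds = 6)
summary(ens)[c("peak_open", "decay_tau")]
#> $peak_open
#> [1] 134.6667
#> $decay_tau
#> [1] 8.920001

spread <- run_ensemble(
  sim_config(geometry = synapse_geometry(cluster_side = 800), seed = 1),
  n_seeds = 6)
summary(spread)[c("peak_open", "decay_tau")]
#> $peak_open
#> [1] 58.16667
#> $decay_tau
#> [1] 9.076934
```

Spreading the same 300 receptors over a 16-fold larger area collapses
the peak (135 → 58 open receptors) while the fitted decay constant
barely moves — de-clustering cannot, in this model, produce a slower
synaptic current.

```r
q10(tau_cold = 47.3, tau_warm = 15.7)   # gamma2L decay constants, 22/32 C
#> [1] 3.012739
q10(60.1, 20.3)                         # gamma1
#> [1] 2.960591
```

Both isoforms accelerate about three-fold per 10 °C — the decay is set by
receptor conformational kinetics, not by transmitter diffusion (which
would give Q10 ≲ 2).

```r
syn <- gen_ipsc_trace(event_rate = 1, decay_tau = 15, noise_sd = 10,
                      duration = 20, seed = 9)
ev <- detect_events(syn$trace, template_decay = 15, threshold = 4)
nrow(ev); median(ev$decay_tau)
#> [1] 16
#> [1] 15.11907
```

All 16 events placed by the generator are found, and the median fitted
decay constant recovers the generating 15 ms within 1%.

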