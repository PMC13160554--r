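---
title: "Modeling representational drift in the olfactory system: methods and design choices"
author: "olfdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling representational drift in the olfactory system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The main olfactory bulb (MOB) is one of the few adult brain regions with
ongoing neurogenesis: granule cells (GCs), the axonless inhibitory
interneurons that form dendro-dendritic reciprocal synapses with
mitral/tufted (M/T) cells, are continuously replaced by adult-born granule
cells (abGCs). Because M/T cells are the sole relay from the bulb to
piriform cortex (PCx), this raises a stability puzzle: how can odor
percepts remain stable when the inhibitory scaffolding of the first relay
is continuously rewired?

`olfdrift` implements a spiking-network model of this circuit to study
that question. The model reproduces two phenomena:

1. **Differential drift.** Daily replacement of 10% of GCs modulates the
   responses of individual M/T cells while their low-dimensional population
   representation stays comparatively stable; downstream PCx responses,
   which integrate M/T input through a threshold nonlinearity,
   reorganize more strongly — representational drift.
2. **Experience-dependent stabilization.** A suppression-model STDP rule
   restricted to abGC-related synapses, combined with repeated daily
   exposure to the same odors, reduces the drift rate of the PCx
   population trajectories relative to a matched no-STDP network.

## Network architecture

Populations (full scale): 50 glomeruli x 25 M/T cells (1250 M/T),
12,500 GCs, 10,000 piriform pyramidal cells (PCs), 1250 feedforward (FFI)
and 1250 feedback (FBI) inhibitory interneurons in PCx. Thirteen synaptic
blocks connect them; each block is defined by a connection density and the
mean of the uniform distribution from which weight magnitudes are drawn
(`default_connectivity_rules()`). Key structural rules:

* M/T cells driven by *different* glomeruli are never connected directly;
  same-glomerulus M/T coupling is dense (0.8) and strong (0.25).
* Each MC→GC synapse carries its own transmission delay, drawn
  Uniform(0, 25] ms and ceiled to the 1-ms grid, so a single M/T burst
  recruits GC inhibition with staggered latencies.
* The centrifugal PC→GC feedback is dense (0.9) but weak (magnitudes
  Uniform(0.01, 0.05)), with a glomerulus-crossing structure: each PC is
  assigned a *primary glomerulus* (the one providing its strongest summed
  feedforward drive) and projects only to GCs *not* reciprocally connected
  to that glomerulus's M/T cells. With feedback off, the block is zero.

Connectivity is sampled as independent Bernoulli draws per ordered cell
pair. Under independent sampling, the expected number of reciprocally
connected GCs per M/T cell is `n_gc x 0.3 x 0.02` (75 at full scale),
substantially below the diagnostic count printed for the original
full-scale network (291 +- 9); no correlated-sampling rule is published
that would produce the larger value, so we default to independent sampling
and expose `reciprocity_boost`, which rewires a stated fraction of each
M/T cell's GC afferents to its own GC out-targets, for users who want to
approach the larger diagnostic. `reciprocal_partner_count()` and
`pc_projection_count()` report both diagnostics; neither is asserted.

### The mini preset and input-scale preservation

The full-scale network (26,250 neurons, and a PC→GC block with ~10^8
nonzeros) is an overnight-class object. The `mini` preset divides every
population by ten (10 glomeruli x 10 M/T, 1000 GCs, 800 PCs, 100 FFIs,
100 FBIs) and keeps all densities. Keeping the *mean strengths* fixed as
well would divide every cell's expected synaptic input by ten (ten times
fewer presynaptic partners at equal density), silencing GCs and PCs and
with them the entire drift phenomenology. We therefore multiply each
block's mean strength by the ratio of full-scale to actual presynaptic
pool size (`preserve_input_scale = TRUE`), which leaves the expected
summed drive per cell invariant and reduces to exactly the published
values at full scale.

This choice preserves mean drive but not higher moments: at 1/10 scale
each PC integrates ~8 active feedforward synapses whose rescaled single
weights approach the spiking threshold, instead of ~100 small ones. PC
recruitment at mini scale is therefore anchored by a few strong synapses
and responds less sensitively to reorganization of M/T rates than the
full-scale threshold-on-a-narrow-sum regime. The practical consequence is
discussed under *Limitations*.

## Neuron and synapse dynamics

Every cell is an Izhikevich neuron,
`dv/dt = 0.04 v^2 + 5v + 140 − u + I`, `du/dt = a(bv − u)`, with reset
`v ← c, u ← u + d` at `v ≥ 30 mV`. Per-cell parameters are drawn once per
network from the per-type generative rules (one uniform `r_i` per cell;
see `draw_izhikevich_params()`), giving regular-spiking to chattering
excitatory cells and fast-spiking/low-threshold interneurons.

Integration is forward Euler with `dt = 1 ms`; the voltage advances in two
0.5-ms half-steps (the standard stabilization for this model) and the
recovery variable once per step using the step-start voltage. Spikes are
recorded at the step on which the threshold was crossed, before reset.
Trials are independent sniffs: state and synaptic channels are
re-initialized to rest (`v = c`, `u = bv`) each trial.

Synapses are jump-and-decay: a presynaptic spike instantly increments the
matching channel of each target by the synaptic weight, and every channel
decays exponentially with `tau = 10 ms`. Channels are segregated by source
class (M/T excitation, GC inhibition, glomerular input and PC feedback for
MOB cells; M/T input, PC recurrence, local inhibition for PCx cells), so
bookkeeping mirrors the current decomposition of the model equations.
MC→GC deliveries pass through a ring buffer honoring each synapse's delay.
Gaussian white noise (SD 1.75 for M/T, 0.8 for GC, 0.9 for PC, none for
FFI/FBI) is added to each cell's current once per 1-ms step; the source
publication states the SDs without a `dt`-scaling convention, and this
per-step convention is fixed here.

## Odors and glomerular input

A model odor activates 6-20% of the glomeruli (3-10 of 50), each with its
own onset latency, as a 90-ms step inside the 250-ms sniff window
(4 Hz sniffing). Latencies are Uniform(0, 160) ms so every step ends
within the window. The default panel has 100 odors; a configurable
fraction (`similarity_mix`, default 0.2) are latency-jittered variants of
earlier odors, which gives the panel pairwise similarities spanning low to
high — independent draws alone produce only low similarity.

During activation, each M/T cell of an active glomerulus receives
`osn_amplitude` plus noise that is half shared across the glomerulus's
M/T cells and half private (`osn_shared_frac = 0.5`), realizing
within-glomerulus input correlation with none across glomeruli. The input
templates are pure functions of the odor: glomerular input is identical
across trials and days, so all drift is circuit-generated.

`osn_amplitude` is not published. It was calibrated once, on the mini
network, to place the model in the regime the source describes: activated
M/T cells fire in the tens of Hz within their activation window (~35 Hz at
the default of 6 current units) and PCx firing is sparse (~10% of PCs
spike in a given trial, ~0.5 Hz population mean). The noise SD on the
glomerular step defaults to 25% of the amplitude.

## Adult neurogenesis as weight reshuffling

Each simulated day, 10% of GCs are replaced: all synapses *of* a cohort
GC — MC→GC afferents (with fresh delays), GC→MC efferents, GC↔GC lateral
connections, and PC→GC feedback afferents — are re-drawn from the same
distributions used to build the network, connectivity included. Cohorts
default to sampling without replacement, so after ten reshuffle days every
GC has turned over exactly once ("almost all" GCs after Day-10). Synapses
not touching the cohort are bit-identical before and after, which keeps
the global weight histograms stationary (verified by two-sample KS tests)
while individual weights and wiring change. `weight_dissimilarity()` (one
minus the Pearson correlation of the flattened GC-related weight entries,
zeros included) tracks cumulative turnover and rises monotonically toward
the independent-redraw plateau.

GC↔GC entries absorb the lateral inhibition attributed to granule cells
*and* short-axon cells; no separate SAC population is modeled.

## STDP (suppression model)

Every pre- and postsynaptic spike carries an efficacy
`eps_i = 1 − exp(−(t_i − t_{i−1})/tau_s)` (first spike: 1; `tau_s` = 34 ms
presynaptically, 75 ms postsynaptically), which suppresses the influence
of bursts. A synapse's update from one trial is
`dw = lr x sum over all pre/post pairs of eps_pre eps_post F(dt)`, with the
asymmetric exponential window `F(dt) = A+ exp(−|dt|/tau+)` for `dt > 0`
and `A− exp(−|dt|/tau−)` for `dt < 0`; `F(0) = 0` (the window is
undefined at zero lag; simultaneous spikes are taken to contribute
nothing). `A+ ~ N(1.03, 0.1)`, `A− ~ N(−0.51, 0.01)`,
`tau+ ~ N(13.3, 1.7) ms`, `tau− ~ N(34.5, 1.6) ms` are drawn once per
synapse (clipped to their valid signs) and survive reshuffling only for
synapses that themselves survive.

STDP acts exclusively on abGC-related synapses: onto abGCs from M/T cells,
GCs/SACs and PCs, and from abGCs onto M/T cells and GCs/SACs. A GC becomes
an abGC on its reshuffle day and stays eligible thereafter (no maturation
window is modeled). Weights are frozen within a trial and updated once at
trial end; all pre/post pairs in the window are used (the efficacy
suppression, not nearest-neighbor pairing, tames bursts). Excitatory
weights clip to `[0, w_cap]`; inhibitory updates act on the magnitude and
clip to `[−w_cap, 0]`, so no synapse changes sign. Two scalings are not
published and are set relative to each block's mean strength:
`learning_rate = 0.01 x |mean|` per pair-sum (gradual trial-by-trial
evolution) and `w_cap = 4 x |mean|` (prevents runaway potentiation). Both
are config-exposed.

Whether reshuffling happens before or after a day's trials is not
specified; the day starts with the reshuffle, then odors are presented.

Two further conventions are exposed because neither is pinned down by the
suppression-model description: the inhibitory update rule
(`inhibitory_update = "magnitude"`, the default, where potentiation
strengthens inhibition, versus `"signed"`, where the signed weight moves
toward zero under potentiation), and `lr_scale`. At the default learning
rate the weights of a freshly reshuffled cohort converge toward their
activity-determined asymptote over roughly two to three simulated days of
repeated presentations — gradual trial-by-trial evolution without
cap-pinning — consistent with asymptotic weight convergence under
repeated experience.

## Analysis pipeline

* **Rates.** Spike counts on the inclusive 0..250 ms sample grid are
  binned with a 5-ms sliding window at 1-ms stride, keeping full windows:
  247 bins.
* **Pooled PCA.** For each population, trial-averaged responses are
  concatenated over all odors and days (cells x bins·odors·days), the
  per-cell mean over all columns is removed, and the eigendecomposition of
  the cells x cells covariance gives a *single* eigenspace for all days,
  making cross-day projections comparable (permuting day blocks leaves the
  eigenvectors unchanged up to sign). The first 50 components define the
  reduced space; the first 3 are used for trajectory visualization
  diagnostics.
* **Population vectors.** The default collapse is *trajectory
  concatenation*: the cells x 247 (or components x 247) response flattened
  into one long vector, so that temporal structure contributes to
  similarity. The alternative reading of the construction — a time-average
  of length `n_cells` — is retained as
  `population_vector(mode = "time_average")`; the two appear
  interchangeably in the source description, and concatenation is the only
  reading consistent with both the "long vector" construction and the
  reported stability asymmetry between the bulb and cortex. Trial-averaged
  statistics (correlation and cosine matrices, drift rates) use
  trajectories; single-trial statistics and decoding use the
  time-collapsed vectors (storing every single-trial trajectory at the
  STDP experiment scale would require ~9 GB).
* **Correlations.** Within-odor day-pair matrices are Pearson correlations
  of the population vectors, averaged over odors; same-day entries compare
  even-trial and odd-trial averages. Across-odor matrices average over 10
  odor pairs drawn once per experiment seed. Cosine similarity uses
  `u·v/(|u||v|)`; same-day entries subtract the within-day variability
  estimate (one minus the even/odd cosine).
* **Drift rate.** The mean over consecutive-day pairs of
  `acos(cosine)` between trial-averaged reduced-space trajectory vectors,
  in degrees/day, averaged over odors. The defining publication points to
  its methods for this quantity without stating a formula; the
  consecutive-day angle is the literal reading of "daily angle changes"
  and recovers a constructed 5°-per-day rotation exactly.
* **Decoding.** Two-class KNN (Euclidean distance, majority vote, ties
  broken toward the nearer class mean) on single-trial projections in the
  50-component space, over the standard grid of training ratios
  (50/70/90%) and K (3/5/7), 30 random stratified splits. The day-wise
  curve trains on Day-0 responses and tests each later day, so decoding
  degrades as representations drift away from the Day-0 reference.

## Experiments

`run_drift_experiment()`: 11 days, daily reshuffle, each day the whole
panel presented for `n_trials` noisy trials (mini: 20 odors x 5 trials;
full scale: 100 x 10); STDP off. `run_stdp_experiment()`: two arms with
identical build/odor/cohort/noise seed streams — one applying STDP after
every trial — under repeated daily presentation of 10 odors x 50 trials;
all 50 trials enter the analysis averages. Every experiment is a pure
function of its configuration: named seed streams (build, cells, odors,
neurogenesis, stdp, noise, analysis) are derived from one master seed, and
noise consumption per trial is independent of network state, so the two
STDP arms see literally identical inputs until plasticity first changes a
weight (day 1).

Problem sizes were chosen so that the full mini drift experiment runs in
minutes and the paired STDP experiment in roughly a quarter hour on a
single core; the full-scale preset reproduces the published architecture
exactly but is an overnight-class computation and is not exercised by the
test suite.

## Numerical and degenerate-case choices

* Euler with half-stepped voltage; divergence (|v| or |u| beyond 1e6, or
  non-finite) raises an error naming the cell and time.
* Delays are ceiled to ≥ 1 ms so every delayed delivery is strictly in a
  later step than its spike.
* `F(0) = 0`; spike-efficacy of a zero interval is 0; the first spike of a
  train has efficacy 1.
* Maximal-distance ties break toward the earliest time bin; PCA
  eigenvalues are clipped at zero; zero-variance vectors raise classed
  errors rather than returning NaN.
* KNN splits are stratified per class so both classes are always
  represented in training; `K` larger than the training set is an error.

## Limitations

* The mini preset preserves mean synaptic drive but not the
  many-small-synapses statistics of the full-scale model. In particular,
  PCx recruitment at 1/10 scale is anchored by a few near-threshold
  synapses per cell, so the gap between bulb stability and cortical drift
  is compressed relative to the full-scale network: a complete granule-cell
  turnover moves M/T trajectory correlations well beyond their trial-noise
  floor but moves PC correlations barely past theirs. Conclusions about
  the magnitude of the bulb/cortex asymmetry should be drawn at full
  scale.
* For the same reason, the drift-*rate* metric at mini scale is dominated
  by its trial-sampling noise floor for the PC population (sparse firing,
  ~0.5 Hz): with the network frozen (no neurogenesis) the consecutive-day
  angle is already ~87% of the value measured under daily reshuffling.
  The neurogenesis-driven component that STDP could in principle remove
  is therefore small at this scale, and in paired mini runs the ongoing
  STDP weight evolution adds more day-to-day variability than it removes
  — the measured drift-rate "reduction" is negative. The STDP
  stabilization magnitude is a full-scale phenomenon; the mini preset
  demonstrates the machinery (paired seed-matched arms, plastic-mask
  bookkeeping, weight convergence), not the effect size.
* Passing tests on synthetic odors demonstrates internal consistency of
  the model and pipeline, not properties of biological recordings: the
  generator holds glomerular input perfectly stable across days and
  samples latencies independently, both idealizations.
* No anatomical geometry, conductance synapses, mitral/tufted distinction,
  AON target, GC survival/apoptosis dynamics, or structural plasticity
  beyond the reshuffling rule.
* The symmetrized KL divergence mentioned alongside the decoding analysis
  in the source is not defined there and is not implemented.
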