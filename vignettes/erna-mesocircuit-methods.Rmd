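---
title: "Models and methods: the STN-GPe mesocircuit and the ERNA analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernasim)
```

# What the package models

Evoked resonant neural activity (ERNA) is the high-frequency evoked
potential that follows each pulse of subthalamic DBS: a first positive
peak (P1) at ~3 ms, an intervening trough, and a second peak (P2) at
~6 ms. The working model of its origin is synaptic: each pulse directly
activates inhibitory GPe-STN afferents (P1) together with excitatory but
rapidly depressing cortico-STN afferents; simultaneously it drives STN
efferents onto GPe and, antidromically, GPe-GPe collaterals. Because the
efferent excitation of GPe is resilient under repetitive activation
while the GPe-GPe inhibition depresses, the net pulse-locked excitation
of GPe grows along a 100 Hz train, and the resulting feedback GPe-STN
inhibition — P2 — grows with it. `ernasim` implements this circuit as an
abstract point-neuron network, plus the empirical analysis pipeline used
to quantify ERNA in microelectrode recordings, plus a synthetic
recording generator that emulates the statistical structure the
pipeline assumes.

# The mesocircuit

## Populations and connectivity

* 100 STN units, Poisson at 39.9 Hz. The source is not itself inhibited
  by GPe feedback in the default configuration: feedback is read out on
  the STN conductance proxy (below). A rate-modulated option
  (`stn_mod_gain`) exposes the alternative reading without asserting it.
* 100 GPe neurons: conductance-based leaky integrate-and-fire
  (`IF_cond_exp`) with C = 200 pF, tau_p = 10 ms (g_L = 20 nS), V_p =
  -65 mV, V_th = -50 mV, V_r = -70 mV, t_ref = 2 ms, E_exc = 0 mV,
  E_inh = -85 mV — conventional point-neuron values; the quantities that
  were actually tuned are the OU noise mean and the efferent weight (see
  "Rate tuning").
* Connectivity: each GPe neuron receives 18-22 STN synapses and 20-25
  reciprocal GPe synapses (the high-connectivity regime; a low 1-5 range
  is available), sampled uniformly without self-connections. Per-synapse
  weights carry lognormal dispersion (sd 0.6 on the log scale, mean 1).
  The dispersion matters beyond realism: the pulse-locked volley of the
  population is decided by a competition between near-simultaneous
  excitation and inhibition, and with identical weights all neurons
  cross threshold together, making the population response a step
  function of the synaptic state instead of the graded growth the data
  show.

## Short-term plasticity

Every DBS-activated projection uses the Tsodyks-Markram model. Between
spikes `u` decays to 0 with `tau_facil` and `r` recovers to 1 with
`tau_rec`; at a spike `u+ = u + U(1-u)`, a quantum `A u+ r` is released
and `r` is depleted by the released fraction. `tau_facil = 0` denotes
the depression-only limit and `tau_rec = 0` a static synapse.

The literature this model descends from reports *fidelities* — the
late-train release amplitude as a fraction of the first pulse under
100 Hz drive — rather than TM parameter values: cortico-STN 10%,
GPe-STN and GPe-GPe 65%, STN efferents 80%. `calibrate_synapse()`
therefore treats the published fidelity as ground truth and recovers
`tau_rec` by bisection at a fixed per-class `U` (and optional
`tau_facil`), using the exact per-pulse recursion
(`tm_release_train()`). The defaults are depression-only classes:
U = 0.5 for cortico-STN (rapid, settling within a few pulses), U = 0.9
for the GPe classes and U = 0.35 for the efferent. Facilitating
parameterizations (`tau_facil > 0`) were evaluated during development;
they can flatten the *steady-state* fidelity across 10-50 Hz, but their
early-train release overshoots at low rates by up to tens of percent,
which injects spurious low-frequency dynamics, so they are not the
default.

Two structural choices deserve explanation:

* **Separate resource pools for pulse-activated transmission.** The
  orthodromic pulse activates its own efferent synapse, distinct from
  the pool used by ongoing Poisson STN traffic (which is modeled
  static). This keeps the "depressing efferent" manipulation what it is
  meant to be — a change in pulse-evoked transmission — instead of
  collapsing the baseline network. A shared-pool variant was tried: the
  collateral pool then sits at its 40 Hz-driven steady state at train
  onset, which removes the rested first pulse but drives the network
  into a saturated-volley regime that inverts the 100 Hz dynamics.
* **The feedback limb of the readout is a rate readout.** Each GPe spike
  contributes a fixed-amplitude GABA-A kernel to the proxy. Putting TM
  state on this limb, driven by continuous background spiking, adds a
  rate-dependent drift (the synapse re-equilibrates from its 40 Hz state
  to its ~100 Hz state over the train) that obscures the circuit
  dynamics under study; the projection's 65% fidelity class is carried
  by the pulse-locked afferent bank instead.

## Noise, integration, readout

GPe background drive is an Ornstein-Uhlenbeck current per neuron,
`dx = -(x - mu)/tau dt + alpha sqrt(2/tau) dW` with tau = 5 ms, updated
by exact discretization (stationary sd equals `alpha` under this
scaling). Integration is fixed-step, dt = 0.1 ms (100 samples per
interstimulus interval at 100 Hz): exact exponential updates for TM
state, conductances, OU and readout kernels; forward Euler for the
membrane voltage. Delays are 1.0 ms for STN->GPe and GPe->GPe
transmission, 1.5 ms from pulse to the afferent readout and 4.0 ms from
a GPe spike to the feedback readout; readout kernels rise with 0.8 ms so
evoked peaks are interior extrema at ~3 ms (P1) and ~6 ms (P2),
matching the analysis windows. The ERNA proxy is the population mean of
the total inhibitory conductance onto STN (non-negative by
construction); its per-pulse P1/P2 series is extracted by the same
analysis code used for recordings.

## Rate tuning

The two free drive parameters were fixed once with the provided
routines: `tune_gpe_bias()` bisects the OU mean against the ~40.5 Hz
off-stimulation GPe rate (giving mu = 332.8 pA at alpha = 120 pA), and
`tune_efferent_weight()` bisects the pulse-activated efferent weight
against ~100 Hz entrainment during a 100 Hz train. The collateral
weight (A_gg = 16 nS at A_eff = 16 nS) sets how strongly early-train
volleys are suppressed; it was chosen so the network reproduces, at
once, ~100 Hz entrainment, P2 growth above 15% at 100 Hz, and growth
abolition in the ablation scenarios.

# The analysis pipeline

All amplitudes are normalized by the pre-stimulation RMS of the 10-250
Hz band-passed trace (zero-phase 4th-order Butterworth; edge transients
trimmed before the RMS), making every statistic gain-invariant. Sweeps
run from a 1.5 ms post-pulse blanking window (the stimulus artifact
lives there) to the end of the interstimulus interval; each sweep
carries its immediate pre-stimulus baseline (mean of the preceding
0.5 ms). P1 and P2 are the dominant local maxima inside configurable
search windows (2-5 ms and 5-9 ms; the windows encode which peak is
which), after a light 0.3 ms moving average for extremum robustness; P1
is measured against the sweep's baseline and P2 against the intervening
trough. A window without an interior local maximum yields a missing
value, never zero. Temporal dynamics are summarized per recording as
mean(pulses 40-45)/pulse 1, separately per peak. Peristimulus time
histograms fold spikes over interstimulus intervals in 0.5 ms bins; the
windowed statistics (4-9 ms amplitude and firing, 5-7 ms trough
firing) feed the two statistical routines: `fit_mixed_slope()` (lmer
random intercept per site, Satterthwaite df; a singular fit — zero site
variance, slope equal to OLS — is flagged, not hidden) and
`within_site_consistency()` (exact Spearman on the n = 3 intensity
triples, a one-sample two-tailed t test of the site rho values against
0, Bonferroni x4 across the module's four hypothesis tests; tied
triples are excluded and reported; a zero-variance rho vector is
reported as degenerate with p -> 0).

# The synthetic generator

Each recording is a template train plus background noise plus a 1 ms
biphasic artifact at each pulse (confined to the blanking window). The
template is three Gaussian lobes (width 0.5 ms, the ~300 Hz look of
ERNA): P1 at 3.2 ms, a trough at 4.75 ms and P2 at 6.3 ms, with the
trough scaled to the P2 lobe (they are two phases of the same resonant
oscillation, while P1 is the direct afferent lobe). Per-pulse
amplitudes approach their late-train values exponentially
(`dynamics_tau` = 8 pulses) so that mean(40-45)/first equals the
configured targets, 0.765 for P1 and 1.395 for P2 at 100 Hz; at 50 Hz
and below both targets are forced to 1 (the frequency specificity of
ERNA is imposed, not emergent, in the generator — the simulator is
where it is emergent). Background noise is integrated white noise
band-limited to 10-250 Hz — the steeply falling (~1/f^2) spectral
profile of LFP — scaled to 12 uV in-band RMS against first-pulse
amplitudes of 150/100 uV; flat-spectrum in-band noise was tried first
and is adversarial to sweep-referenced peak measures because it
decorrelates between a peak and its baseline reference 3 ms away.
Spiking is an inhomogeneous Poisson process thinned by
`exp(-gain * rectified ERNA / 150 uV)` with refractory deletion; the
default gain 6 roughly halves interstimulus firing in the 4-9 ms
window at 100 uA. Intensity (30/50/100 uA) scales the template
linearly, so larger evoked waveforms come with deeper suppression by
construction; sites carry lognormal amplitude factors (sd 0.2, a free
parameter, not a claim about patient variability).

What passing tests on this generator do show: the pipeline's
segmentation, normalization, peak logic, dynamics ratios, PSTHs and
statistics recover known ground truth through realistic noise. What
they do not show: performance on real microelectrode signals with
non-stationary artifacts, unit instability, or waveform shapes outside
the three-lobe template; spike sorting is out of scope entirely
(synthetic spikes carry timestamps).

# Problem sizes and runtimes

The shipped configurations are desk-scale by design: 10 seeded 5 s
network simulations per rate estimate, 60-pulse trains x 10 iterations
per scenario, 12- or 20-site cohorts of 10 s recordings at 10 kHz. The
compiled core integrates ~1 s of network time in ~0.15 s, so the whole
acceptance computation completes in well under a minute and the test
suite in a few minutes.

# Known limitations

* **50 Hz partially engages the synaptic dynamics.** With TM depression
  calibrated to the 100 Hz fidelity targets, the GPe-class recovery
  time constant comes out near 10 ms, so transmission still depresses
  by ~13% at 20 ms intervals. The network amplifies the difference
  between the rested first pulse and that steady state, and the
  in-silico P2 ratio at 50 Hz comes out near 1.4 — a genuine, clearly
  flagged deviation from the flat-at-LFS picture (10, 20 and 30 Hz are
  flat). No TM parameterization we found satisfies the 100 Hz fidelity
  targets and full recovery at 20 ms simultaneously: depression-only
  classes cannot recover that fast, and facilitating classes that
  flatten the steady state overshoot in the early train. Treat 50 Hz
  simulations as a transition regime of this model rather than a
  reproduction of the flat empirical curve.
* With a strongly depressing efferent, late-train pulse-locked GPe
  firing collapses and late P2 peaks become undetectable; the dynamics
  ratio is then undefined (missing, per the analysis contract) and
  "undetectable late P2" is reported — a stronger form of growth
  abolition, handled explicitly by the ablation checks.
* The first pulse of any train meets a rested network and rested
  synapses; its volley is systematically atypical, and all dynamics
  ratios inherit that reference. This mirrors the empirical definition
  (ratios are referenced to the first pulse) but makes single-pulse
  references noisy; the generator-side cohort tolerances (±0.05/±0.07)
  absorb it.
* No long-term plasticity, no multi-compartment morphology, no
  extracellular forward model, no GPi/SNr populations: the proxy is a
  synaptic-conductance readout, not a simulated field potential.
* The removal of intrinsic GPe-GPe connectivity disinhibits the model
  GPe (baseline and entrained rates rise well above the tuned targets);
  the ablation is interpreted only through the P2-growth contrast, not
  as a calibrated physiological state.
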