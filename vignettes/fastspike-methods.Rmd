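---
title: "Methods: quantifying a fast-spiking phenotype, optogenetic connectivity, and single-cell expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying a fast-spiking phenotype, optogenetic connectivity, and single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastspike)
```

fastspike implements the three quantitative pipelines used to characterize a
fast-spiking, glutamatergic neuron class in acute slice experiments:

1. **Intrinsic electrophysiology** — passive membrane properties and
   action-potential (AP) features from current-clamp step protocols;
2. **CRACM connectivity** — light-evoked EPSC measurement, pharmacological
   block verification, and population connectivity from voltage-clamp sweeps;
3. **Single-cell RT-qPCR** — relative expression by the 2^-ddCt method with a
   limit-of-detection rule.

Because slice recordings of this kind are rarely deposited, the package ships
generators that produce recordings with *known* ground truth, so every
extraction stage has a parameter-recovery test rather than a visual check.
This vignette documents the models, the defaults and the numerical choices.

## Conventions

All traces live on a 10 kHz sample grid (0.1 ms), the standard digitization
rate for these protocols. Time is in milliseconds from sweep start; voltages
in mV as recorded (no liquid-junction-potential correction); currents in pA
with inward currents negative. Stimulus timing is metadata carried with each
sweep, never inferred from the trace. A step command switching at time
`t_on` affects the first sample *after* `t_on`, so the sample at the onset
time still belongs to the baseline; the extraction code assumes the same
convention when it aligns fits to the stimulus.

On disk a recording is a `#`-headed, tab-delimited text file (one column per
sweep, one row per sample, values at 17 significant digits). Plain text was
chosen deliberately: fixtures stay diff-able and language-neutral, and a
write/read cycle is bit-exact.

## The model neuron

The current-clamp generator integrates an adaptive exponential
integrate-and-fire (AdEx) membrane with a first-order H-current:

$$C\,\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
  - w - g_h\,h\,(V - E_h) + I(t)$$
$$\tau_w\,\dot w = a (V - E_L) - w,\qquad
  \tau_h\,\dot h = h_\infty(V) - h,\qquad
  h_\infty(V) = \frac{1}{1 + e^{(V+80)/8}}$$

AdEx was chosen because it reproduces high-frequency, minimally accommodating
trains with a handful of interpretable parameters; a conductance-based Kv3
model would add little for a recovery target and much for maintenance. The
H-current is the minimal mechanism for the depolarizing sag seen on
hyperpolarizing steps: `h` activates below about -80 mV with time constant
`tau_h`, producing a slow relaxation back toward rest.

Two numerical choices matter:

* **Fixed-step forward Euler at the sampling interval.** Simulated traces
  land exactly on the 0.1 ms grid the extractors operate on, so there is no
  resampling step between generation and analysis. The discretization biases
  the effective membrane time constant by about `-dt/2` (0.4% at
  `tau = 13 ms`), far inside the recovery tolerances.
* **Stereotyped spike waveform.** Once `V` passes the spike-initiation point
  `V_T + 3 Delta_T`, the exponential term diverges within a fraction of a
  sample — the AdEx "spike shape" is not a resolved waveform at any step
  size. The integrator therefore emits the transient as a fixed,
  sample-aligned script: a capped initiation sample, two rise samples to
  `v_peak` (the logged spike time), a two-sample repolarization, then
  `v_reset` held for an absolute refractory period. Every simulated spike
  consequently has an identical shape, which is exactly what ground truth
  for amplitude/half-width/fAHP extractors should look like; it also means
  the simulator has *no* spike-broadening mechanism, making it a null model
  for the broadening statistic. The refractory period (default 1 ms) bounds
  the firing rate the way sodium-channel recovery does in real membranes.

### The default preset

`neuron_params()` defaults describe a fast-spiking cell: `C = 40 pF`,
`g_L = 3 nS` (R = 333 MOhm, tau = 13.3 ms), `E_L = -66 mV`, `V_T = -42 mV`,
`Delta_T = 1 mV` (steep initiation), `V_reset = -55 mV`, `V_peak = 0 mV`,
weak spike-triggered adaptation (`a = 0`, `b = 5 pA`, `tau_w = 30 ms`) so
trains accommodate little, and `g_h = 0.25 nS` (`E_h = -30 mV`,
`tau_h = 50 ms`) calibrated so the -100 pA sag ratio sits near the 0.96
observed in this cell class. Current noise is 5 pA per sample. The preset is
configuration, not ground truth: recovery tests draw `g_L` and `C` across
[2, 6] nS x [20, 80] pF.

```{r preset}
neuron_params()
```

## Passive-property extraction

All deflections are measured relative to the per-sweep pre-stimulus baseline,
not absolute potentials; this makes `input_resistance()` invariant to a
constant voltage offset and keeps the sag ratio well defined when the
baseline drifts.

* **Resting potential** — mean of the pre-stimulus baseline across sweeps,
  emulating the value read immediately after break-in.
* **Input resistance** — OLS slope of steady-state deflection against
  injected current over hyperpolarizing (and 0 pA) steps. "Steady state" is
  the final 10% of the step (50 ms of a 500 ms step) — the defining
  protocols say only "at the end of" the step, and 50 ms averages enough
  samples to make the point estimates essentially noise-free. Sweeps
  containing spikes are excluded automatically with a warning.
* **Membrane time constant** — single-exponential fit to the rising phase of
  the mean -100 pA response, restricted to the segment from onset until the
  trace first reaches 63.2% ($1-e^{-1}$) of its steady-state deflection.
  The baseline and the steady-state deflection are pinned to their
  long-window estimates and `tau` is the only free parameter: on the short
  0-63.2% segment a three-parameter fit is poorly conditioned (`dV` and
  `tau` trade off against each other) and recovery errors roughly double.
* **Sag ratio** — steady deflection over peak hyperpolarizing deflection,
  both baseline-relative (the defining ratio leaves absolute-vs-relative
  ambiguous; deflections are the offset-invariant choice). Values
  marginally above 1 (sampling noise on a sag-free cell) are clipped to 1
  with a warning.
* **Capacitance** — reported as `tau_m / R_in` and labelled *derived*: the
  amplifier dialog readout used in rigs is not available to an offline
  pipeline, and the two measurements need not agree numerically.

## Spike detection and AP features

The detector accepts local maxima above -10 mV preceded within 2 ms by a
membrane-potential derivative of at least 20 V/s, with a 1 ms minimum
separation. Derivatives are central differences at native sampling with no
smoothing: at 10 kHz the derivative of a sub-millisecond AP is already well
resolved, and smoothing would bias the 20 V/s threshold crossing. The AP
threshold is found by walking back from the peak to the start of the
contiguous run of samples with dV/dt >= 20 V/s; its resolution is therefore
one sample (0.1 ms).

Half-widths are measured at the voltage halfway between threshold and peak
with linear interpolation between samples — at 0.1 ms sampling an
interpolation-free crossing would quantize a 0.45 ms half-width by >20%.
The fAHP trough is searched from the peak to the next spike (or 10 ms for
the last spike); its amplitude is threshold-relative and its latency is
referenced to the threshold-crossing time on the rising phase (the defining
phrase "time difference between the AP threshold level and the fAHP peak"
is ambiguous between the rising-phase crossing and the falling-phase
re-crossing; the rising-phase time is the conventional anchor and is what
the package uses).

Single-AP features come from the first spike of the lowest 20-100 pA step
that evokes one. Broadening is `(HW2 - HW1)/HW1` on the step at twice that
current; when the exact doubled amplitude was not tested, the nearest
available step is used with a warning.

Train-level measures: the I-f curve counts spikes in the 500 ms step window;
population curves average across cells per current, omitting cells not
tested at an amplitude. The maximal firing frequency is taken on the largest
step below the first step showing *AP failures* — a term the defining
protocols leave undefined. The package's criterion, applied to each step: an
aborted spike (a local maximum between spikes that exceeds the measured
threshold level but misses the -10 mV detection bar), or cessation of
spiking during the last 100 ms of the step despite earlier spikes
(depolarization block). Accommodation metrics (late/early rate ratio and
fractional amplitude attenuation over the first and last 100 ms) summarize a
phenomenon the source protocols describe only qualitatively; they are the
package's own formulas and are labelled derived in reports.

## CRACM analysis

Light-evoked EPSCs are measured on the pointwise average of ten consecutive
sweeps (0.1 Hz stimulation makes trials independent). Baseline is the 50 ms
pre-light mean; the amplitude is the drop from baseline to the trace minimum
in a 1-20 ms post-light window — the monosynaptic latency range; a window is
needed because an unbounded minimum over the sweep would grow with sweep
length under noise. Amplitudes are reported as positive magnitudes of the
inward current.

Connectivity classification — `amplitude > max(4 pA, 5 x baseline sd)` — is
the package's own rule (the protocols report connected counts without
stating a criterion). It is configurable and logged with each measurement.
The 4 pA floor keeps residual currents under glutamate-receptor block
(~2.5 pA) unconnected even on very quiet baselines; the 5-sd term controls
false positives on noisy ones. One caveat documented deliberately: because
the amplitude is a windowed *minimum*, it acquires an extreme-value bias of
roughly the averaged-trace noise sd. At connected-cell amplitudes this is
negligible; at near-floor amplitudes (a blocked current of 2-3 pA under
4 pA single-sweep noise) the measured block ratio is biased upward by a few
hundredths. The block-ratio recovery tests therefore run at 2 pA noise,
where the bias is inside the +/-0.02 band.

Population connectivity reports counts, the percentage to two decimals, and
an exact Clopper-Pearson 95% interval (computed via `stats::binom.test`;
the test suite checks it against a brute-force binomial tail inversion).

## qPCR 2^-ddCt

Technical triplicates collapse to an arithmetic mean after dropping
replicates above the limit of detection (Ct > 37, strictly — a Ct of
exactly 37.0 survives) and wells with no amplification curve; a (cell, gene)
with no surviving replicate is censored. Per cell,
`dCt = Ct_target - mean(Ct_references)` — the arithmetic mean of the two
reference Cts is equivalent to a geometric mean of reference expression.

The calibrator for the second difference is genuinely open, and the choice
changes what the numbers mean:

* `"cohort"` (default) — each gene's cohort-mean dCt; values are
  fold-changes relative to the cohort average *of that gene* and center
  on 1. Appropriate when the question is between-cell variability.
* `"none"` — plain `2^-dCt` relative to the reference genes. This is the
  only form that preserves abundance ratios *between* genes, so cross-gene
  comparisons and all recovery tests use it.
* a cell id — a designated calibrator sample (e.g. a positive-control
  cell).

Cells with a censored reference gene are excluded with a warning; censored
targets yield censored outputs with per-gene `n` reflecting the exclusions
in the summaries (mean, median, quartiles, s.e.m.).

The plate generator draws `Ct = base - log2(abundance) + N(0, sd)` with
per-replicate dropouts; the default panel mirrors the study design (Pvalb
and Vglut2 references, Kv3.1/Kv3.2/Hcn2 targets at comparable abundance,
Vgat placed beyond the detection limit).

## What the generators do and do not emulate

The generators reproduce the *protocol structure* (step series, light-pulse
trials, triplicate plates), the deterministic physics of a point-neuron
membrane, and simple white current noise. They do not emulate
electrode-series-resistance artifacts, bridge imbalance, slow drift,
temperature effects, correlated (1/f) noise, channel stochasticity,
cell-to-cell parameter variability beyond what a test draws explicitly,
polysynaptic latencies, or qPCR efficiency differences between assays.
Passing recovery tests therefore shows the extraction math is correct under
clean, known-truth conditions — not that the pipeline is robust to every
artifact of real rigs. That separation is intentional: correctness of the
formulas and robustness to artifacts are different claims, and only the
first is testable without deposited recordings.

## Problem sizes and determinism

The bundled checks use sizes chosen to exercise the statistics while staying
desk-scale: 20 simulated cells for passive recovery, a 33-step protocol
(-100 to 1500 pA in 50 pA increments) for detector equivalence and the
phenotype checks, 200 generator runs each for classification power and
false positives, and 8-cell plates for expression recovery. Every generator
is bit-reproducible given `(params, seed)`; the acceptance script derives
all sub-seeds from its single `--seed` argument.

## Known limitations

* The AdEx preset is a caricature: its AP amplitude (~39 mV from threshold,
  given the fixed `V_peak = 0 mV` cutoff) and fAHP latency are smaller than
  typical measured values for this cell class, and its maximal firing
  frequency is bounded by the refractory period rather than by
  channel kinetics. Recovery tests target quantities with analytic ground
  truth (R = 1/g_L, tau = C/g_L, logged spike times), not tabulated
  population means from real neurons.
* Threshold, and hence amplitude and half-width anchors, resolve to one
  sample (0.1 ms); sub-sample threshold interpolation is deliberately not
  attempted.
* The connectivity criterion and the AP-failure rule are package-defined
  operationalizations of undefined terms; both are configurable and any
  comparison across datasets should state them.
* `capacitance()` will not numerically match an amplifier's compensation
  readout; it is a consistency-derived quantity.
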