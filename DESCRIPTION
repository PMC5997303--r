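Package: fastspike
Title: Intrinsic Electrophysiology, Optogenetic Circuit Mapping, and
    Single-Cell qPCR Analysis for Fast-Spiking Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the fast-spiking electrophysiological
    phenotype of genetically identified neurons from whole-cell
    current-clamp recordings: passive membrane properties (resting
    potential, input resistance, membrane time constant, sag ratio,
    derived capacitance), single action-potential features (dV/dt
    threshold, amplitude, half-width, latency, fast
    after-hyperpolarization), train-level measures (I-f curves, maximal
    firing frequency, spike-frequency accommodation, amplitude
    attenuation, spike broadening), channelrhodopsin-assisted circuit
    mapping (CRACM) analysis of light-evoked excitatory postsynaptic
    currents with pharmacological-block verification and binomial
    connectivity summaries, and 2^-ddCt relative quantification of
    triplicate single-cell RT-qPCR cycle-threshold tables with a
    limit-of-detection rule. A bundled adaptive exponential
    integrate-and-fire simulator (with an H-current sag mechanism), a
    light-evoked EPSC sweep generator and a qPCR plate generator provide
    ground-truth recordings so that every extraction stage has a
    parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
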