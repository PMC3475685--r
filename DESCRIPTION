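Package: lamcor
Title: Laminar Cortex Model Simulation of Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates local field potentials (LFPs) of a laminar cortical
    area with a five-layer continuum (population mean-field) model. Each
    cortical layer (I, II/III, IV, V, VI) is a two-dimensional grid of
    elements holding an excitatory and an inhibitory neuron population;
    layers are coupled through a laminar synaptic connection map with
    conduction delays, and external drive arrives through thalamic and
    cortico-cortical afferents. Includes visual-stimulation protocols
    (spontaneous noise, constant stimulation, intermittent light,
    transient point sources), laminar LFP aggregation, FFT power spectra
    and band powers, 1/f spectral-exponent fitting, harmonic detection
    for steady-state visual evoked potentials, and one-dimensional
    current source density analysis with three-point Hamming smoothing,
    plus end-to-end experiment scenarios (synaptic-gain sweeps, layer-IV
    synapse reduction, laminar band-power profiles, point-source CSD,
    SSVEP entrainment, PSP time-course sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
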