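Package: crtgaze
Title: Spiking Cortico-Reticulo-Thalamic Circuit Model of Attentive Gaze Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a closed-loop spiking neural network model of the
    cortico-reticulo-thalamic (CRT) circuit that tracks or fixates a visual
    stimulus via a retinotopic motor error map. Izhikevich neuron populations
    (thalamus, thalamic reticular nucleus, middle- and deep-layer cortical
    pyramidal neurons, parvalbumin and calbindin interneurons) interact through
    saturating-differential synaptic conductances (AMPA, NMDA, GABA-A, GABA-B),
    gap junctions, low-threshold T-type calcium channels, and a disinhibitory
    short-term plasticity mechanism by which deep cortical firing weakens
    reticulo-thalamic inhibition. Includes the inhibitory perturbation
    protocols that produce schizophrenia-like oculomotor deficits, parametric
    sweep orchestration, and the analysis metrics (epoch spectra, rms gaze
    error, high-velocity movement counts) used to quantify them.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
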