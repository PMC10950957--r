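Package: loomnet
Title: Spiking Neural Network Simulation of Visual Looming Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feed-forward spiking neural network that detects looming
    (approaching) objects in grayscale video. Frame differences are split
    into ON/OFF polarity channels, converted to weighted spike trains by
    eight-phase binary coding, pooled through a foveated (eccentric)
    receptive-field layer of leaky integrate-and-fire neurons, and passed
    through a competition between excitatory and phase-delayed inhibitory
    currents with feed-forward inhibition gating a single output neuron.
    Includes a synthetic stimulus generator (looming, receding, translating
    and grating clips), delay-sweep and down-sampling ablation experiments,
    and spike-raster export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
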