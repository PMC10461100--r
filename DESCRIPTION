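Package: tcikit
Title: Quantification of Transcuticular Calcium Imaging for Odorant
    Receptor Deorphanization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for transcuticular calcium imaging (TCI)
    screens of insect odorant receptors expressed in the Drosophila
    empty-neuron system. Converts raw GCaMP fluorescence recordings
    (multi-frame TIFF stacks or per-ROI trace tables) into
    bleach-corrected dF/F0 traces and response amplitudes, assembles
    fly-by-stimulus response matrices, characterizes receptor tuning
    (lifetime sparseness, frame-resolved cross-correlation against
    electrophysiological reference profiles), fits variable-slope Hill
    dose-response curves (EC50, Hill coefficient), and measures
    recording longevity under repeated stimulation. Includes a
    generative simulator of GCaMP recordings (photobleaching, probe
    kinetics, sensor noise, latent odorant tuning shared with a
    simulated single-sensillum-recording channel, Hill dose dependence,
    response adaptation) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    tools,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
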