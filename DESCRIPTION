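Package: drgquant
Title: Automated Quantification of Immune Signals in DRG Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An automated, bias-free quantification pipeline for multi-channel
    fluorescence images of dorsal root ganglion (DRG) tissue sections and
    cultured sensory neurons. Segments neuron somata from a pan-neuronal
    marker (PGP9.5) while excluding nerve fibers, measures per-neuron mean
    pixel intensity (MPI) of MHCII after shrink/grow mask logic removes
    signal from satellite glia and bright non-neuronal immune cells,
    classifies MHCII-positive neurons against an isotype-control
    99th-percentile threshold, detects sub-cellular MHCII puncta above local
    background, scores surface-MHCII polarization on cultured neurons,
    classifies RFX1-positive nuclei, counts CD3+CD4+ T cells per mm2 of
    neuron-containing tissue, and converts soma areas to diameters for
    small/large size classification. A synthetic ground-truth image
    generator renders DRG-like scenes with complete truth tables so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
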