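Package: ssnmsi
Title: Spatial Similarity Networking for Tandem Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deconvolution and annotation of tandem mass spectrometry
    imaging (MS2I) data by spatial similarity networking (SSN). Reads mzML
    runs with interleaved full-scan FTMS and targeted ion-trap MS2 spectra,
    reconstructs product-ion images on a pixel grid, scores pairwise spatial
    similarity (cosine, SSE, MSE), clusters product ions by connected
    components (plain and patch-based coherent variants), reconstructs
    deconvoluted cluster spectra, and matches clusters against a product-ion
    library with accurate-mass precursor assignment and a five-level
    annotation confidence scale. Also models parallel image acquisition
    (PIA) timing and geometry (duty cycle, inclusion-list cycling, pixel-size
    scaling) and ships a ground-truthed synthetic MS2I phantom generator that
    writes mzML, so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mzR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
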