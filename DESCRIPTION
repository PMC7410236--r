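Package: gliamorphdyn
Title: Microglial Morphodynamics from Time-Lapse Imaging and EEG State Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies microglial morphology and motility from fluorescence
    imaging, together with EEG-based anesthesia state profiling. Provides
    FFT cross-correlation drift registration of 4D time-lapse stacks,
    standard-deviation z-projections, box-counting (Hausdorff) fractal
    complexity, a frame-subtraction motility index normalized to stack
    volume, skeleton-graph morphometry (complexity index, covered
    environment area, ramification statistics), EEG spectral analysis
    (Welch spectra, width at mid-height, amplitude distributions, sliding
    FFT spectrograms), and the matching statistical layer (paired t-tests
    with d'Agostino-Pearson screening, Kruskal-Wallis with Sidak-corrected
    post-hoc comparisons). A seeded synthetic-data generator produces
    ground-truthed branched cells, motile drifting time-lapse stacks and
    anesthesia-state EEG traces so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    igraph,
    EBImage,
    tiff,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
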