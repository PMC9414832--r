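Package: iondecon
Title: Spectral Deconvolution with Mass-Spectral Subtraction for GC/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ion-ratio target matching and iterative mass-spectral subtraction
    for unit-mass GC/MS and heartcut GC-GC/MS data. Implements reduced-ion-
    intensity qualification (average reduced-intensity deviation, scan-to-scan
    variance, Q-value and Q-ratio criteria), invariant-scan averaging,
    iterative component subtraction until residuals approximate background,
    cumulative target-library building across heartcuts with Kovats retention
    indices, and downstream multi-sample comparison (detection, Venn
    partitioning, fold-change reports) for volatile-compound profiling.
    Includes a seeded chromatogram simulator with known ground truth and a
    packaged green/roasted-coffee abundance fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    mzR,
    yaml
Config/testthat/edition: 3
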