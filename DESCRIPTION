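Package: casasim
Title: Synthetic Semen Microscopy Videos and Benchmarks for CASA Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric simulation of 2-D grayscale human-semen microscopy
    videos with exact per-frame ground truth, for benchmarking
    computer-assisted semen analysis (CASA) image-processing algorithms.
    Sperm cells are rendered from point-spread functions (an anisotropic
    Gaussian head, a clipped Laplacian-of-Gaussian membrane halo, and a
    Laplacian-of-Gaussian flagellum ridge) and moved by four kinematic swim
    models (circular, linear mean, hyperactive Brownian, immotile), with
    optional positional jitter, per-cell intensity attenuation, and Markov
    swim-mode transitions.  The package also ships the evaluation side of the
    benchmark: five segmentation and localization detectors (Otsu, Bradley
    adaptive, spot enhancement, Sobel edge, Gaussian-mixture background
    subtraction), four multi-target trackers on a shared constant-velocity
    Kalman core (NN, GNN, PDAF, JPDAF), the OSPA point-set metric,
    assignment-based precision and recall, CLEAR-MOT (MOTP/MOTA) scoring, and
    scripted noise-sweep and tracking benchmarks with tidy tibble reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
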