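Package: betadyn
Title: Nonlinear Dynamics of Beta-Band Neurophysiological Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed nonlinear time-series analysis of beta-band (13-30 Hz)
    MEG and EMG recordings during sustained isometric contraction: zero-phase
    FFT cosine band-pass filtering, delay embedding with mutual-information
    delay and false-nearest-neighbour dimension selection, Rosenstein largest
    Lyapunov exponent, Higuchi fractal dimension and Grassberger-Procaccia
    correlation dimension per 10 s window, Hilbert-envelope burstiness
    (coefficient of variation of the slow-normalized envelope), cross-modal
    envelope correlation, phase-randomized surrogate testing, and the
    group-level statistics (paired and one-sample t tests, Cohen's d,
    noncentral-t post hoc power).  A synthetic-data module generates canonical
    dynamical systems with known invariants and paired pseudo-MEG/EMG
    beta-band cohorts with planted burstiness and shared envelope modulation,
    so the full pipeline can be exercised end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
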