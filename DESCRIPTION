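Package: cidyn
Title: Condition-Independent Neural Dynamics and Submovement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing corrective reaching behaviour and the
    condition-independent (CI) rotational dynamics of motor cortical
    populations that accompany it. Cursor trajectories from a precision
    center-out task are decomposed into discrete initial and corrective
    submovements via speed-peak detection with prominence criteria. Spike
    trains are binned, smoothed, and reduced with PCA plus a
    skew-symmetric (jPCA-style) dynamics fit to locate the neural plane
    with the strongest rotational CI activity; the instantaneous phase of
    population activity in that plane (CI phase) is obtained with the
    Hilbert transform and refined by iterative phase-averaging, with
    trial-wise cross-validation. CI-phase timing predictions are compared
    against a firing-rate regression baseline using circular statistics
    and variance-ratio tests. A synthetic-session generator with
    Gaussian-bump speed profiles, cosine-tuned inhomogeneous Poisson
    units, and full ground truth makes every stage testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
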