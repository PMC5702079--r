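Package: pobds
Title: Estimation and Identification of Partially-Observed Boolean Dynamical Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partially-observed Boolean dynamical systems (POBDS):
    Boolean gene regulatory networks whose binary state evolves under
    Bernoulli transition noise and is observed only through a noisy
    measurement channel (Bernoulli, Gaussian, Poisson, or negative binomial,
    matching microarray and RNA-seq data). Provides a BoolNet-dialect
    network parser, synchronous-dynamics attractor analysis, simulation of
    paired state/observation time series, the exact Boolean Kalman filter
    and smoother (optimal MMSE state estimators over the enumerated state
    space), a sequential importance resampling particle approximation for
    large networks, and multiple model adaptive estimation for identifying
    the network topology and process-noise intensity from expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
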