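Package: diffent
Title: Intracellular Anomalous Diffusion, Generalized Entropy and
    Phase-Separation Homogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-particle-tracking analysis of intracellular diffusion
    and its thermodynamic interpretation. Simulates fractional Brownian
    trajectories, DIC-like image stacks and phase-separated fluorescence
    images with known ground truth; segments and links objects into
    trajectories; fits the anomalous-diffusion power law MSD = 2n*K*t^a;
    maps the fitted (K, a) to a generalized (Gaussian differential)
    entropy and total-energy scale; decomposes the diffusion power into
    elasticity and mechanical-work components via a depleted-arm
    regression; quantifies cell-content homogeneity as the coefficient
    of variation of pixel intensities; and runs the paired
    active/ATP-depleted cohort statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ggplot2
Config/testthat/edition: 3
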