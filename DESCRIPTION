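Package: ctviqa
Title: Quality Assurance for CT Ventilation Imaging Under Quantum Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how quantum (photon) noise and noise-reduction
    preprocessing affect CT-based ventilation imaging (CTVI). Provides a
    deterministic digital analogue of a nonrigid alveoli phantom with known
    diaphragm-driven deformation, additive Gaussian noise simulation, slice-wise
    median filtering and a small 2-D U-Net denoiser trained with an L1 loss,
    multi-step B-spline free-form deformable registration with bending-energy
    and Jacobian penalties, Jacobian-determinant ventilation maps, and
    consistency metrics (target registration error against landmarks, tertile
    category agreement with Cohen's kappa, 2-D histograms and Spearman
    correlation), plus an orchestrated experiment runner comparing noisy,
    median-filtered and CNN-denoised pipelines against a noiseless reference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
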