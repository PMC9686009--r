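Package: mvmar
Title: Metal Artifact Reduction in CT via MV-CBCT Synthetic-CT Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for megavoltage cone-beam CT (MV-CBCT) based metal
    artifact reduction in kilovoltage CT. Provides a seeded simulator of
    paired head-like kV-CT / MV-CBCT slices with filtered back-projection
    physics (beam hardening, photon starvation, Poisson noise), the three
    hyperbolic-tangent HU scaling transforms used to condition network
    inputs, a toy-scale cycle-consistent adversarial translator with a
    deterministic surrogate, HU-range fusion of translated candidates with
    dual-threshold metal segmentation and copy-back, image-quality metrics
    (PSNR, SSIM, HU-banded variants, CT-number to relative-electron-density
    conversion), and a dosimetry evaluation stack (toy exponential-attenuation
    dose engine, global gamma analysis, DVH metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
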