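Package: phantomiq
Title: Synthetic CT Phantom Simulation and Image-Quality Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Catphan-style computed-tomography quality-assurance
    phantoms with exactly known ground truth (insert CT numbers, Gaussian
    edge blur, noise magnitude and noise texture) and measures the standard
    image-quality metrics on them or on real image stacks: rotated line-ROI
    CT numbers and attenuation profile curves, image noise magnitude, the
    radial-frequency noise power spectrum with unit-area normalization, the
    circular-edge (disk) modulation transfer function with f50/f10 readout,
    a non-prewhitening model-observer surrogate for low-contrast
    detectability, and Cohen's kappa for inter-rater agreement. A protocol
    runner orchestrates multi-condition studies and emits report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
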