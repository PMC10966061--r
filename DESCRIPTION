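Package: stegomed
Title: Region-of-Non-Interest Data Hiding for Medical Images via Block DCT
    Quantization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conceals a QR-coded patient payload inside the medically
    insignificant (background) region of 12/16-bit grayscale medical images
    and recovers it exactly. Embedding quantizes the coefficients of 4x4
    block discrete cosine transforms of background tiles into beta intervals
    of [0, 4], carrying one message bit per insignificant pixel. Includes
    minimal DICOM and 16-bit PNG input/output, a deterministic
    threshold-based segmentation stand-in with an adapter for external
    segmenters, a self-contained QR encoder/decoder with Reed-Solomon error
    correction, imperceptibility metrics (MSE, PSNR, NCC, IoU), seeded noise
    attacks for robustness evaluation, and a synthetic phantom generator so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
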