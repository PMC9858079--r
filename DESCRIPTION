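Package: beatgram
Title: ECG Beat Delineation and Time-Frequency Image Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning single-lead electrocardiogram recordings into
    labeled image datasets for rhythm classification. Provides a synthetic ECG
    generator with analytic ground-truth fiducials, signal preprocessing
    (zero-phase band-pass filtering, Daubechies-8 multiresolution wavelet
    denoising and baseline removal, amplitude normalization, half-peak-to-peak
    trimming), Pan-Tompkins style R-peak detection with zero-crossing
    delineation of P, QRS and T waves, three time-frequency representations of
    extracted wave segments (short-time Fourier spectrogram, polar "irisgram",
    and continuous-wavelet scalogram), rendering to fixed-size RGB images with
    stratified 70/30 and k-fold splits, and a pluggable lightweight image
    classifier with confusion-matrix based reporting (per-class sensitivity,
    precision, overall accuracy, k-fold summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    nnet,
    png,
    EBImage,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
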