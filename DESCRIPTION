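Package: stressfuse
Title: Multimodal Acute-Stress Detection from ECG, Voice and Facial Expressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for multimodal acute-stress detection.
    Implements ECG denoising and autocorrelation-based heartbeat relocation,
    Mel-spectrogram voice features, aligned face-frame clip extraction with a
    pluggable face detector, compact residual 2D and inflated-3D convolutional
    classifiers with a temporal squeeze-excitation attention module, and a
    matrix principal-eigenvector late-fusion rule that combines per-modality
    stage posteriors into a calm/stress decision. Ships a seeded synthetic
    multimodal data generator and a stratified k-fold evaluation harness so
    the full pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
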