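Package: broeeg
Title: Blink-Related Oscillation Extraction for Low-Density Frontal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extraction and dual-system comparison of blink-related
    oscillations (BROs) from four-channel frontal EEG. Implements
    template-matching blink detection on the vertical EOG channel,
    short-time Fourier transform binary-mask time-frequency denoising of
    blink-locked epochs, ocular contamination index (OCI) quantification,
    time-domain component (C1/C2) and Morlet-wavelet frequency-domain
    feature measurement, and paired statistics (paired t, Wilcoxon
    signed-rank, Pearson correlation, intraclass correlation and
    Monte-Carlo permutation tests). Includes a ground-truthed synthetic
    EEG generator emulating paired textile-like and dry-like electrode
    recordings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
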