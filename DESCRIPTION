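Package: fecgtools
Title: Fetal ECG Extraction and Delineation from Abdominal Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the fetal electrocardiogram (FECG) from multichannel
    maternal abdominal recordings by combining negentropy-based FastICA with
    an over-relaxed Newton iteration and R-synchronized rank-2 singular value
    decomposition of the beat matrix. Includes an improved wavelet
    modulus-maxima delineator for QRS waves, P/T waves and ST segments based
    on the quadratic-spline derivative wavelet, detection and signal-quality
    metrics (eigenvalue and cross-correlation SNR, Se/PPV/F1), readers for
    WFDB and CSV records, and a synthetic abdominal maternal+fetal ECG
    simulator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
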