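Package: abipwv
Title: Ankle-Brachial Index from ECG and Photoplethysmography Pulse Wave
    Velocity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the ankle-brachial index (ABI) from simultaneously
    sampled electrocardiogram (ECG) and photoplethysmography (PPG) streams.
    Signals are denoised with a powerline notch filter and Symlet-4 wavelet
    stages, cardiac landmarks (ECG R-peaks, PPG systolic peaks) are detected,
    per-beat pulse transit times are converted to pulse wave velocities using
    height-derived arterial path lengths, and the ABI is reported as the
    foot-to-hand pulse wave velocity ratio averaged over a 30-second window.
    Includes a seeded synthetic ECG/PPG generator with ground-truth
    annotations, the embedded 22-subject validation table, and clinical
    method-agreement statistics (tolerance-band concordance, mean absolute
    error, Bland-Altman limits of agreement).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
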