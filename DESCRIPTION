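Package: hoofbeat
Title: Band-Power Profiling and Stability Analysis for Ambulatory Equine EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterises ambulatory electroencephalography (EEG) recordings
    from freely moving horses by their "EEG profile": the relative power of
    the alpha (8-12 Hz), beta (12-30 Hz) and gamma (>30 Hz) bands, expressed
    as proportions of their summed power. Provides EDF/EDF+ input and output,
    automated artifact masking, segmentation into 500 ms epochs, per-epoch
    FFT power spectra with per-frequency +/-3 SD outlier-epoch rejection,
    hemisphere comparison and pooling, and inter-/intra-individual
    coefficient-of-variation stability statistics. A calibrated synthetic
    generator produces single recordings and multi-horse, multi-session
    cohorts with known band composition, injected movement artifacts and
    controlled between- and within-individual dispersion, so that every
    stage of the pipeline can be validated without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
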