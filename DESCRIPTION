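Package: oscipat
Title: Oscillatory Pattern Detection in ECoG/EEG via Wavelet Skeletons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transient oscillatory patterns in electrophysiological
    time series (ECoG/EEG) with a continuous Morlet wavelet transform and a
    skeleton (ridge) method: temporally linked local maxima of the wavelet
    energy surface are chained into ridges, duration-filtered into patterns,
    and assigned by mean frequency to six fixed analysis bands (1-14 Hz).
    Per-episode normalized pattern counts and durations are computed for
    annotated sleep/wake episodes, and recordings (baseline, post-exposure,
    recovery) are compared with symmetric ratio statistics classified against
    a band of minor deviations. Includes a synthetic ECoG-like signal and
    cohort generator (1/f background plus enveloped bursts) with full ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
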