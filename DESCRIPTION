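Package: tcss
Title: Time-Causal and Time-Recursive Temporal Scale-Space Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale smoothing and analysis of uniformly sampled temporal
    signals under strict time causality. Implements cascades of first-order
    recursive filters (the discrete analogue of truncated-exponential
    smoothing kernels), the scale-covariant time-causal limit kernel with
    logarithmically distributed scale levels, scale-normalized temporal
    derivatives and temporal N-jets, moment-based fitting of limit-kernel
    models to ex-Gaussian kernels and to measured response functions,
    mappings to Koenderink's scale-time model, and time-causal wavelet and
    time-frequency (spectrogram) transforms computed time-recursively.
    Includes generators for synthetic test signals (Wiener paths,
    frequency-varying sines, multi-scale peak trains) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
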