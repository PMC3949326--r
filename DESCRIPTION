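Package: lipstab
Title: Neural Field Model of Trans-Saccadic Visual Stability in Area LIP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-coded neural field simulator of the lateral intraparietal
    area (LIP) circuit for visual stability across saccades.  Two populations
    of gain-field neurons combine a retinal stimulus signal with a
    proprioceptive eye-position signal and a corollary-discharge signal,
    producing predictive receptive-field remapping.  A competing-accumulator
    readout turns population activity into forward/backward displacement
    reports, reproducing saccadic suppression of displacement (SSD), the
    blanking effect, and the behavioural consequences of ablating remapping
    feedback or corollary discharge.  Results are returned as tibbles with
    broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
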