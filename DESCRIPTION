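Package: nestnet
Title: Nest-Digging Activity Recognition from Accelerometer Biologging
    with Tiny Input-Delay Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies tortoise nest-digging versus non-digging activity
    from single-axis accelerometer time series using small input-delay
    neural networks (a plain variant, a local-receptive-field variant and
    a weight-shared variant) trained by backpropagation, combined with a
    three-feature filter over the per-segment output stream of the
    network. Includes the signal preprocessing chain (moving-average
    filtering, integer normalization, down-sampling), a synthetic
    generator for the three activity classes (digging, walking, eating),
    end-to-end evaluation over multiple weight initializations, and the
    memory-footprint accounting that justifies deployment on
    memory-constrained biologging devices.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
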