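Package: sociometer
Title: Active-Inference Simulation of Self-Esteem as a Sociometer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-state active-inference engine (variational and expected
    free energy, fixed-point state inference, habit-and-precision weighted policy
    selection, Dirichlet evidence accumulation) together with affective-charge
    precision dynamics and a two-level generative model of self-esteem, in which
    slowly learned trait self-esteem modulates the precision of fast state-level
    sociometer inference. A configurable synthetic social niche supplies
    action-contingent approval, neutral and rejection feedback with
    controllability and scheduled regime shifts, and scenario runners reproduce
    qualitative predictions about behavioural volatility, learned helplessness,
    anxiety buffering and sociometer tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
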