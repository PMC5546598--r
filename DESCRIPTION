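Package: biospice
Title: Circuit-Style Simulation of Biochemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact SPICE-like netlist language for biochemical systems
    (binding, enzymatic, diffusion, Hill, translation, pump, transcription
    and custom rate laws), its translation into the equivalent dynamical
    network under the electronics analogy (species as charge-storage nodes,
    degradation as leaks, reactions as signed controlled sources), and a
    multi-analysis engine: steady state and multistability search, stiff
    transient simulation with pulse/waveform stimuli, DC sweeps with
    continuation, small-signal transfer functions (Bode analysis) and
    truth-table logic runs. Includes bidirectional SBML (Level 3)
    conversion, an NGSPICE-netlist exporter, generators for repressilator
    gene-regulatory-network and random metabolic-pathway benchmarks, and
    tidy results with ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    xml2,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
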