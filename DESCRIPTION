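Package: brainmass
Title: Whole-Brain Neural Mass Networks with Conduction Delays and Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-brain activity as a network of three-population
    Wilson-Cowan-type neural mass oscillators (excitatory, subtractive-inhibitory
    and divisive-inhibitory populations per region) coupled through a structural
    connectome with axonal conduction delays. Inter-region weights are initialized
    from streamline tractography counts and delays from fiber lengths at a fixed
    propagation speed. The delay differential system is integrated with a
    fixed-step Bogacki-Shampine explicit Runge-Kutta (2,3) scheme using cubic
    Hermite dense output over a circular history buffer, giving bounded memory
    over day-long biological horizons. Hebbian plasticity with synaptic
    normalization updates inter-region and intra-region weights on a fixed
    cadence. Includes a synthetic connectome generator, sparse snapshot recording
    with disk spill, broom-style tidiers, ggplot2 autoplot methods, and an
    operation-count scaling benchmark.
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
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
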