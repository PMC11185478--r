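Package: spatialQSSA
Title: Quasi-Steady-State Reductions of Enzyme Kinetics in Heterogeneous Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates enzyme-catalyzed reactions in spatially heterogeneous
    domains and assesses when quasi-steady-state model reductions remain
    valid. Implements the full mass-action reaction-diffusion model, its
    standard (Michaelis-Menten) and total quasi-steady-state reductions in
    one dimension, and a two-dimensional Goldbeter-Koshland
    phosphorylation-dephosphorylation cycle, all advanced by Lie operator
    splitting with an implicit cosine-spectral diffusion substep under
    zero-Neumann boundary conditions. Ships deterministic generators for
    homogeneous, tanh-step, Gaussian-localized and striped initial-condition
    families, validity-condition diagnostics, spatial-average and
    initial-velocity summaries, and parameter-sweep drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
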