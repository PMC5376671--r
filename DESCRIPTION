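Package: hoxmir
Title: Simulation of Hox-MicroRNA Network Dynamics and Boundary Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional tissue of cells patterned by opposing
    retinoic acid (RA) and fibroblast growth factor (FGF) gradients, in which a
    small gene-regulatory network of Hoxa5 and Hoxc8 (mRNA and protein) plus a
    hypothetical microRNA ('mir-x') sets the rostrocaudal expression boundary
    between adjacent motor-neuron identities. Each cell follows
    sigmoidal-relaxation ordinary differential equations driven by noisy
    steady-state morphogen gradients. The package scores boundary robustness
    (transition widths and boundary distance), enumerates and screens the 324
    candidate mir-x network topologies to extract consensus interactions,
    and reproduces mutant (Dicer-null, fast-miRNA) and temporal-delay analyses
    of the coherent feed-forward loop that filters transcription noise.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
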