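Package: wfeval
Title: Multi-Objective Evaluation of Water-Fertilizer Orthogonal Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing and evaluating water-fertilizer coupling
    trials on an L9(3^4) orthogonal array: Taguchi-style range analysis,
    water use efficiency and partial factor productivity, indicator
    weighting by the classical and an exponential-form entropy weight
    method, and treatment ranking by TOPSIS extended with virtual positive
    and negative ideal solutions. Includes a synthetic trial generator
    with known ground truth (additive factor effects plus multiplicative
    Gaussian plot noise) so every pipeline stage can be validated by
    parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
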