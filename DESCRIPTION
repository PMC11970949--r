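Package: morseopt
Title: Multiple Optimal Solutions for Integer Linear Programs via Random
    Objective Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Finds multiple distinct optimal solutions of integer and mixed
    integer linear programs by the MORSE procedure: multiplicative random
    perturbation of objective coefficients with an instance-adaptive radius
    epsilon chosen so that every optimum of the perturbed instance is an
    optimum of the original. Includes an MPS reader/writer, a two-phase
    simplex and branch-and-bound solver, an exhaustive and cut-based
    all-optima enumeration oracle, solution-set diversity metrics (pairwise
    Hamming distance curves, multiset and per-variable Shannon entropy),
    and synthetic minimum hitting-set generators emulating single-cell
    gene-target selection instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    boot,
    optparse
Config/testthat/edition: 3
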