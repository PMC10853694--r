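Package: enzalloc
Title: Optimal Enzyme Allocation in Unbranched Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and numerical solutions for the optimal allocation of a
    fixed enzyme budget along an unbranched metabolic pathway. Implements the
    trivial, Michaelis-Menten, thermodynamic, mass-action and Haldane rate
    laws together with their efficiency factorization; closed-form optimal
    enzyme and metabolite profiles where they exist and a convex enzyme-cost
    minimizer over log-concentrations where they do not; a metabolic control
    analysis layer (elasticities, flux and concentration control coefficients,
    summation and connectivity theorems, enzyme-control and enzyme-elasticity
    rules); and a coarse-grained three-sector cell model that yields Monod
    growth parameters from enzyme kinetics.
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
    withr
Config/testthat/edition: 3
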