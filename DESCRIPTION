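Package: porestates
Title: Combinatorial Pore-State Analysis and Stochastic Kinetics of
    Single-File Water Transport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing osmotic versus diffusive water transport
    through single-file membrane pores such as aquaporins. Enumerates and
    classifies pore occupancy states (water, one tracer, one vacancy),
    computes the osmotic-to-diffusive permeability ratio Pf/Pd from the
    state counts under the tracer-state and tracer-exit-state models and
    under competing literature expressions, and provides an exact
    continuous-time Markov (Gillespie) simulator of the knock-on collision
    and Brownian hop mechanisms together with a master-equation stationary
    solver that serves as an exact oracle for small pores. A command-line
    interface exposes state censuses, the model comparison table, the
    simulator and ratio scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
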