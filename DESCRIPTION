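Package: intrec
Title: Thermodynamically Consistent Kinetic Models of Serine Integrase
    Recombination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetic models of site-specific DNA recombination by
    a serine integrase and its recombination directionality factor (RDF).
    Builds reversible reaction networks for plasmid and linear substrates,
    enforces energy conservation around the recombination cycle (Wegscheider
    closure), integrates the stiff ODE systems, computes per-step Gibbs
    free-energy landscapes, finds equilibrium compositions, runs concentration
    scans, fits parameters to experiment-shaped recombination data under
    thermodynamic constraints, and generates synthetic datasets with the
    triplicate time-course / endpoint design used for model calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
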