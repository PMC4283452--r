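Package: soflc
Title: Self-Organizing Type-2 Fuzzy Logic Control for Closed-Loop
    Anesthesia Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A closed-loop anesthesia-control sandbox. Simulates a
    multivariable pharmacokinetic/pharmacodynamic patient model in which
    intravenous atracurium drives neuromuscular block (through a
    transfer-function pharmacodynamic path and a Hill concentration-effect
    curve) and inhaled isoflurane lowers mean arterial pressure, with an
    interaction path from isoflurane to paralysis, parametric model noise
    and measurement noise. The plant is regulated by a self-organizing
    fuzzy logic controller (SOFLC) available in type-1, interval type-2
    and zSlices general type-2 variants, with Mamdani min-max inference,
    Karnik-Mendel type reduction, a performance-index driven rule
    modification layer, firing-percentage bookkeeping and trivial-rule
    extraction. Includes the two-stage surgical simulation protocol,
    steady-state-error and control-stability metrics, repeated-run
    nonparametric comparison, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
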