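Package: cellmlgen
Title: CellML Electrophysiology Models: Parsing, Singularity Fixes,
    Analytic Jacobians and Solver Code Generation
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Parses CellML 1.0 electrophysiology models (components,
    connections, physical units, content MathML and RDF metadata
    annotations) into a symbolic intermediate representation built on R
    language objects.  Detects removable 0/0 singularities of
    Goldman-Hodgkin-Katz form f(V)*(V - v0)/(exp(B*(V - v0)) - 1) in model
    equations and repairs them with piecewise linear interpolation over a
    narrow interval around the singular voltage, derives analytic Jacobian
    matrices by symbolic differentiation, decomposes gating equations for
    backward-Euler and Rush-Larsen updates, converts tagged interface
    quantities to millivolts, milliseconds and microamperes per square
    centimetre, and renders solver-ready code from templates.  A
    deterministic synthetic-model generator with planted singularities
    supports fully offline testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    xml2
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
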