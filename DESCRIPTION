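Package: polyligand
Title: Mechanics, Thermodynamics and Kinetics of Ligand Binding to
    Biopolymers Under Tension
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative modelling of small ligands (such as
    single-stranded DNA binding proteins) binding to long biopolymers
    held under mechanical tension. The partially covered polymer is
    decomposed into naked regions, described by an extensible
    worm-like chain, and ligand-covered regions, described by a
    freely-jointed chain, giving a coverage-dependent force-extension
    relation. Equilibrium coverage as a function of force is obtained
    by Gibbs free-energy minimisation with ideal-gas or Tonks-gas
    (hard-rod) ligand statistics, the latter in closed form via the
    Lambert W function. Binding kinetics with one, two, or
    interconverting binding modes are integrated as ODE systems and
    converted to extension time series. Fitting routines recover
    coverage, binding-mode geometry, and effective rate constants from
    force-extension curves and extension traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
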