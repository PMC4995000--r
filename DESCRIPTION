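Package: tcellcommit
Title: Dynamical Modelling of T-Cell Lineage Commitment by Combinatorial
    Logic Compilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the gene-regulatory dynamics of early
    T-cell lineage commitment with a minimal four-gene network (TCF-1,
    GATA-3, BCL11B, PU.1) driven by Notch signalling. All 32 combinatorial
    AND/OR configurations for the regulation of BCL11B by Notch, TCF-1 and
    GATA-3 (with monomer or dimer valencies) are enumerated and compiled
    into Shea-Ackers thermodynamic rate laws, yielding a family of ODE
    models. The package converts stage-indexed expression profiles to time
    series, fits model parameters in a constrained two-leg procedure
    (Notch-bound derivation, multi-objective fitting of the TCF-1/GATA-3/
    BCL11B subsystem with PU.1 clamped, then PU.1 estimation by constrained
    simulated annealing), filters candidate fits by confidence-interval
    coverage and half-life plausibility, and classifies commitment as
    reversible or irreversible by bifurcation analysis over the maximum
    Notch level. Models can be exchanged as SBML Level 3 documents, and a
    synthetic-data generator provides benchmark datasets with the
    statistical structure of staged expression measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
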