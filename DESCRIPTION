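Package: fragopt
Title: Fragment-Based Hybrid RHF:MP2 Energies, Gradients and Restrained
    Reaction-Path Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-body effective fragment molecular orbital (EFMO) energies with
    frozen-domain-and-dimers (FDD) bookkeeping, a hybrid scheme in which a single
    high-level fragment receives an MP2 correlation energy and gradient on top of
    an otherwise RHF-level fragment expansion, classical many-body polarization
    via self-consistent atom-centered induced dipoles, analytic gradients on
    active-domain atoms, and restrained geometry optimization with adiabatic
    mapping of reaction paths.  A pluggable electronic-structure backend contract
    with a deterministic closed-form mock engine makes the whole framework
    testable without an SCF program.  Includes XYZ/PDB readers, a fragment/domain
    spec format, synthetic water-cluster and toy-reaction fixtures, and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
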