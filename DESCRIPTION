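Package: kfba
Title: In Vivo Kinetic Parameter Estimation and Kinetically Constrained
    Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates in vivo kinetic parameters of central Escherichia
    coli metabolism from multi-omic (flux, metabolite, protein) chemostat
    data by weighted-sum-of-least-squares nonlinear optimization, and
    translates the fitted parameters plus concentration measurements into
    per-reaction kinetic flux bounds that tighten constraint-based flux
    predictions through a mixed-integer kinetic flux balance analysis
    (KFBA) program.  Ships a curated central E. coli stoichiometric
    network, a 19-reaction simplified kinetic model with a 36-parameter
    registry, thermodynamic distance-from-equilibrium analysis, and a
    synthetic chemostat study generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    quadprog,
    stats,
    tools,
    utils,
    yaml,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
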