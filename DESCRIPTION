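Package: nmrbind
Title: NMR Dilution, Diffusion and Chemical-Shift-Perturbation Analysis
    of Ligand-DNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of solution NMR experiments that probe
    how small aromatic ligands, such as camptothecin derivatives, bind a
    nicked DNA duplex.  Implements the isodesmic (indefinite, equal-K)
    self-association model with per-proton nonlinear fitting of dilution
    chemical-shift series, estimation of 1:1 ligand-DNA binding constants
    from diffusion-ordered spectroscopy (DOSY) coefficients under fast
    exchange, chemical-shift-perturbation (CSP) mapping of the binding
    site relative to the nick, and seeded synthetic-data generators so
    every stage can be exercised and validated without instrument data.
    Functions take and return tibbles and compose with the pipe; fitted
    objects have tidy() and glance() methods and ggplot2-based plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
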