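Package: crisprspread
Title: Epidemiological and Evolutionary Dynamics of CRISPR-Cas Spread in
    Mixed Bacterial Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic modelling of how a CRISPR-Cas immune system
    spreads through a bacterial population exposed to lytic phage. Implements
    a five-genotype bacteria-phage ODE system (sensitive, surface-resistant
    and spacer-immune cells, with and without a CRISPR-Cas locus), the
    resistance-frequency difference statistic f-delta and its reduced
    frequency dynamics, a mass-action horizontal gene transfer extension,
    a generator of synthetic short-term competition experiments emulating
    the Pseudomonas aeruginosa PA14 / DMS3vir design, and the accompanying
    statistical analysis (FDR-corrected baseline tests, a linear model of
    CRISPR-positive frequency change with bootstrap confidence intervals,
    and sign-prediction validation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
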