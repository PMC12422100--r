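Package: syntroflux
Title: Stoichiometric Flux and Cross-Feeding Analysis for Synthetic Anaerobic Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proteomics-informed stoichiometric flux analysis of
    defined anaerobic co-cultures degrading cellulose to methane and carbon
    dioxide. Converts daily fed-batch metabolite measurements (aqueous
    concentrations and headspace partial pressures) into cumulative net
    production, fits nonnegative per-species overall-reaction extents by
    weighted nonnegative least squares with optional shrinkage toward
    proteomics-derived activity priors, infers interspecies exchange
    networks, computes transformed Gibbs energies from reaction quotients,
    tracks carbon and electron-equivalent transfer to products, and provides
    the comparison statistics (Student's t, Benjamini-Hochberg, Pearson,
    capped fold changes) used to contrast community assemblies. Includes a
    seeded synthetic-data generator emulating the fed-batch culture design so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
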