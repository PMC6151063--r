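Package: astigvec
Title: Alpins-Method Astigmatism Vector Analysis and Standard Polar Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized Alpins-Method vector analysis of pre- and
    post-operative astigmatism for refractive-surgery outcome reporting.
    Reads five-column cylinder datasets (XLSX or CSV), normalizes cylinder
    notation, mirrors left-eye axes, computes the target-induced (TIA),
    surgically-induced (SIA) and difference (DV) vectors plus the
    correction index (CI) per eye via double-angle decomposition, and
    renders the four standard single-angle polar plots with shaded
    orientation sectors, exported as high-resolution TIFF images. Includes
    a synthetic-cohort generator with known ground-truth correction
    parameters and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    ggplot2,
    optparse,
    readxl,
    stats,
    tibble,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
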