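Package: pamkin
Title: Kinetic Analysis of Real-Time Peptide Microarray Kinase Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for real-time peptide microarray (PamChip-style)
    tyrosine kinase assays. Extracts initial phosphorylation velocities from
    progress curves by exponential-association fitting, calls substrates from
    background thresholds and enzyme/ATP dose dependence, estimates Km(ATP),
    apparent Vmax and catalytic efficiency (Vmax/Km) from the linear low-[S]
    regime, applies fold-change and percent-of-total comparison transforms,
    and builds catalytic-efficiency-weighted substrate motif matrices. Ships
    the JAK2 JH1/JH1-JH2/V617F substrate screen and catalytic-efficiency
    reference tables as fixtures, and a full synthetic-assay generator so
    every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
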