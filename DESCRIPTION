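Package: teashuttle
Title: Antioxidant, Electron-Shuttle and Network-Pharmacology Profiling of
    Tea Extracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline pipeline for characterising bioactive compounds in
    semi-fermented (Oolong) tea extracts. Quantifies phytochemical content
    and antioxidant activity from plate-reader absorbances via linear
    calibration, percent radical-scavenging activity and IC50
    interpolation; computes microbial-fuel-cell power densities and
    blank-normalised amplification factors together with cyclic-voltammetry
    closed-loop areas and cycle-attenuation profiles; screens compound
    libraries with Lipinski, Veber and absorption filters plus an
    ortho/para-dihydroxy electron-shuttle structural rule; calls
    differentially expressed genes per breast-cancer subtype with an
    empirical-Bayes moderated t-statistic and Benjamini-Hochberg
    adjustment; ranks protein-protein-interaction hub genes by maximal
    clique centrality, maximal neighbourhood component, degree and harmonic
    closeness with top-k consensus; and performs hypergeometric GO
    over-representation analysis. A synthetic-data module generates every
    input class with known ground truth so the whole pipeline is testable
    without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    pracma,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    igraph,
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
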