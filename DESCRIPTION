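Package: aquassay
Title: Binding Isotherms, Water-Permeability Kinetics and Assay Statistics
    for Membrane-Transport Biophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for ligand-binding and water-transport assays
    centred on the aquaporin-4 (AQP4)-calmodulin axis. Fits
    depletion-corrected one-to-one binding isotherms to microscale
    thermophoresis (MST) titrations, sigmoidal dose-response curves for
    inhibitor IC50 determination, double-exponential stopped-flow shrinkage
    kinetics with conversion to osmotic (Pf) and single-channel (Pu) water
    permeabilities, calcein-quench cell-volume kinetics, and
    membrane-accumulation half-times. Also provides tissue water-content,
    perivascular-enrichment, positive-pixel and compound-action-potential
    summaries, the two-population Z-test on fitted binding constants,
    Kruskal-Wallis with Conover-Iman post hoc comparisons, and
    Bonferroni-corrected pairwise t tests. Seeded generators emulate every
    assay so the full pipeline is testable without instrument data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
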