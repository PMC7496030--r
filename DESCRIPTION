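Package: mampep
Title: Multi-Attribute Method Peptide Monitoring for Monoclonal Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open implementation of a targeted peptide-mapping (multi-attribute
    method) workflow for monoclonal antibody quality attributes: in-silico
    tryptic digestion with missed cleavages, monoisotopic mass and isotope
    envelope computation for PTM-modified peptides (deamidation, oxidation,
    succinimide formation, N-glycosylation, C-terminal lysine loss),
    extracted-ion-chromatogram quantitation from centroided MS1 mzML at ppm
    tolerance, site-level relative-abundance rollup, sequence-coverage and
    digestion QC metrics, and intra-/inter-laboratory precision statistics
    (RSD and one-way ANOVA variance components). A seeded synthetic LC-MS run
    generator emulates multi-laboratory tryptic-digest studies, including
    retention-time drift and forced-degradation series, so the full pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
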