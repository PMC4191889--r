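Package: HistoneCensus
Title: Target-Decoy PSM Validation, Spectral-Count Quantification, and
    Histone PTM Occurrence Census for Shotgun Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of shotgun (MudPIT-style) proteomics
    search output for chromatin samples. Implements per-subgroup linear
    discriminant validation of peptide-spectrum matches against a
    reversed-sequence decoy database with nonparametric (kernel density)
    posterior peptide probabilities, decoy-based false discovery rate
    estimation, protein assembly with shared-peptide spectral-count
    distribution, NSAF and emPAI abundance indices, assignment of histone
    post-translational modifications from mass deltas, cross-species
    residue coordinate mapping by global alignment, construction of a
    per-sample PTM occurrence census, and two-sample (sperm versus
    embryo chromatin) comparative statistics. A seeded synthetic
    peptide-spectrum-match generator provides ground-truth-labelled
    input so the whole pipeline is testable without raw spectra.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Epigenetics
RoxygenNote: 7.3.3
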