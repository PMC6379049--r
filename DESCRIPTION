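Package: atlasomics
Title: Quantitative mRNA-Protein Atlas Analytics and Proteogenomic Candidate
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired transcriptome/proteome tissue
    atlases: log/median normalization, five-class tissue-specificity
    calls, ranged major-axis (model II) regression of protein on mRNA,
    proteomic-ruler protein and mRNA copy numbers, correlation and
    co-inertia (RV) analytics, construction of proteogenomic search
    spaces (sample-specific, variant, alternative translation
    initiation site and lncRNA databases), in-silico protease
    digestion, candidate-peptide filtering with per-criterion audit
    trails, and validation of endogenous spectra against synthetic
    references via the normalized spectral contrast angle. A synthetic
    data generator emulates the statistical structure of the study
    inputs so the whole pipeline runs and is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
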