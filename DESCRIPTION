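Package: methfidelity
Title: Methylation-Based Fidelity Assessment of Tumor-Derived Cell Cultures
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses how faithfully tumor-derived cell cultures preserve the
    epigenome of their parental tissue from Infinium-style methylation array
    intensities. Provides probe quality filtering, beta/M-value computation and
    BMIQ normalization; copy-number (log2R) profiles against copy-neutral
    controls with genomic binning and cell-versus-tissue similarity tertiles;
    PCA-initialized t-SNE embedding with HDBSCAN clustering and DBCV validity;
    kernel-smoothed differentially methylated region calling with per-region
    delta-beta scores; probe-bias-aware (Wallenius) and Fisher gene-set
    enrichment; and the combined DNAm-by-CNV six-condition fidelity taxonomy.
    Ships a synthetic Infinium-style cohort generator with planted class
    signatures, DMRs and CNV segments so the whole pipeline is testable
    end-to-end without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
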