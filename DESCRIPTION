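Package: tcrep
Title: TCR Repertoire Comparison by Spectratype Perturbation and Clonotype Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to compare T-cell receptor (TCR) repertoires across sorted
    T-cell populations. Implements CDR3 spectratype analysis (per-TRBV
    CDR3-length profiles, deviation from a reference profile, and bounded
    perturbation scores), clonotype-level statistics on deep-sequencing count
    tables (depth normalization by random downsampling, resampled clonotype
    sharing, Shannon/Pielou-based clonality, Morisita-Horn overlap, and
    predominant-clonotype tables), hierarchical clustering with
    multiscale-bootstrap approximately-unbiased (AU) cluster support, PCA and
    ANOVA group comparison with Holm adjustment, plus a synthetic repertoire
    and spectratype simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
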