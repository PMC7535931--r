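Package: m6apipe
Title: miCLIP m6A Site Calling, Quantification and Multi-Omic Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls N6-methyladenosine (m6A) sites from miCLIP pileups using a
    crosslink-induced-mutation (CIMS-style) procedure with DRACH motif
    filtering, quantifies per-site and per-transcript m6A abundance as
    normalized-to-input uTPM and SN-uTPM (full-length and per 5' UTR / CDS /
    3' UTR region, with per-nucleotide densities and metagene profiles),
    integrates transcript m6A scores with ribosome-profiling translation
    efficiency (quintile binning, ECDF comparison, Wilcoxon rank-sum tests,
    hypergeometric gene-set overlap and preranked GSEA), and integrates with
    two-condition single-cell RNA-seq expression via per-population Welch-type
    Z scores with +/-1.96 classification. A synthetic-data generator emulates
    the statistical structure of the corresponding experimental designs so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
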