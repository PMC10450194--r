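Package: thermoproxy
Title: Sequence-Based Proxies for Bacterial Optimal Growth Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating thermal adaptation of bacteria from
    ribosomal gene sequences. Classifies metal-binding (C+) versus
    metal-free (C-) isoforms of nine ribosomal proteins by zinc-ribbon
    motif patterns, detects temperature-associated conserved residues by
    comparing cold- and heat-adapted consensus sequences, computes 16S
    rRNA GC/U content (whole-molecule and helical-segment) and the
    YVIWREL amino-acid content of protein sets, and relates every proxy
    to optimal growth temperature with ordinary least squares fits,
    confidence and prediction bands, temperature binning and outlier
    detection. Ships a fully seeded synthetic-data generator so the whole
    pipeline can be exercised and validated without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
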