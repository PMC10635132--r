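Package: movebwt
Title: Move-Structure Full-Text Index for Pangenome Sequence Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and queries move-structure indexes over the run-length
    Burrows-Wheeler transform (RLBWT) of pangenome sequence collections.
    The index is a single table with one row per BWT run supporting
    LF-mapping by row arithmetic plus bounded forward scans
    ("fast-forwards"), with an optional run-splitting mode that makes every
    LF-mapping query constant-bounded. On top of LF-mapping the package
    computes pseudo matching lengths (PMLs) with threshold-directed
    repositioning, and occurrence counts via backward search, including an
    interleaved multi-read batch driver. Brute-force suffix-array/BWT/LCP
    oracles, a synthetic pangenome and read generator, and a command-line
    interface are included so every query path can be verified exhaustively
    against ground truth without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
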