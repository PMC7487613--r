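Package: flowcram
Title: Reference-Based Lossless Compression of Ion Torrent Flow-Signal BAM Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses Ion Torrent aligned BAM files by separating the
    per-read integer flow-signal vectors (the ZM auxiliary tag) from the
    rest of the alignment, grouping reads mapped to the same locus, delta
    encoding the flow vectors within each group, and compressing the
    resulting streams with a selectable general-purpose backend (gzip, xz
    or zstd).  The flow-free body is converted to CRAM through samtools
    when a reference genome is available, and everything is packaged in a
    single reversible tar archive.  Includes an optional lossy binning
    transform for the flow values, space-saving and flow-content metrics,
    and a seeded simulator of Ion Torrent-like flowgrams and BAM fixtures
    with a threshold base caller.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
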