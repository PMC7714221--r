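Package: seqvault
Title: Content-Addressed Local Repositories of Biological Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build and query local, non-redundant, content-addressed
    collections of nucleotide and protein sequences. Sequences are keyed by
    a truncated SHA-512 digest (sha512t24u: first 24 bytes, unpadded
    URL-safe base64), stored append-only in BGZF-compressed FASTA volumes
    with faidx/gzi indexes for fast random access to slices, and annotated
    with a timestamped multi-namespace alias database supporting CURIE
    identifiers, identifier translation and naming history. Includes
    hard-link incremental snapshots, a read-only REST service that also
    speaks the GA4GH refget protocol, a command-line interface, and a
    seeded synthetic FASTA generator for reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    DBI,
    GenomicRanges,
    IRanges,
    RSQLite,
    Rsamtools,
    httpuv,
    jsonlite,
    openssl,
    utils
Suggests:
    callr,
    curl,
    digest,
    fs,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
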