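# seqvault

Local, non-redundant, content-addressed repositories of biological
sequences for R.

Bioinformatics pipelines — variant validation and normalization above
all — need fast, stable, private access to the genome, transcript and
protein sequences they reference. Remote accession services add network
latency, rate limits and reproducibility risk; plain FASTA collections
are redundant and carry no identifier management. seqvault stores
sequences once, keyed by content, with fast random access to arbitrary
slices, a timestamped multi-namespace identifier database, hard-link
snapshots, a command-line tool, and a read-only HTTP service that also
speaks the GA4GH refget protocol.

## The core convention: sha512t24u

Every sequence is addressed by a digest of its (uppercased) residues:

```
sha512t24u(seq) = base64url( SHA-512(seq)[1..24 bytes] ),  unpadded
```

a fixed 32-character, URL-safe key. The truncation keeps the standard
SHA-512 initialization vector, so the 24-byte digest is a prefix of any
longer truncation of the same input. Under the birthday bound,

P(collision) ≈ 1 − exp(−n(n−1)/2^(b+1)),

a corpus of n = 10^18 sequences at b = 192 bits has collision
probability below 10^-21 (`collision_probability(1e18, 192)` evaluates
to `7.96546e-23`). Each stored sequence additionally gets hex MD5, hex
SHA-1 and SEGUID identifiers, so digest-based and conventional
accessions translate freely in both directions.

Sequences live in immutable, timestamped, BGZF-compressed FASTA volumes
with faidx/gzi indexes (htslib, via Rsamtools), so fetching a slice
decompresses only the slice. Identifiers are CURIEs
(`namespace:alias`); reassigning an alias to a different sequence
deprecates the old association instead of overwriting it, preserving the
full naming history.

## Worked example

```r
library(seqvault)

root <- file.path(tempdir(), "readme-repo")
seqvault_init(root)
sv <- seqvault(root, writeable = TRUE)

sv_store(sv, "GATTACAGATTACA", "refseq:DEMO_1.1")
#> $n_seqs_added        [1] 1
#> $n_aliases_added     [1] 5     # 4 computed identifiers + 1 supplied
sv_commit(sv)                    # finalize the BGZF volume

# 0-based, half-open slices, by any identifier
sv_fetch(sv, "refseq:DEMO_1.1", 3, 8)
#> [1] "TACAG"

sv_translate_identifier(sv, "refseq:DEMO_1.1")
#> [1] "MD5:a0ae76be441aae7d2cbdc50ba00af74f"
#> [2] "SEGUID:tT0FNeOAZL7H8djrdpNdzxpoVaU"
#> [3] "SHA1:b53d0535e38064bec7f1d8eb76935dcf1a6855a5"
#> [4] "ga4gh:SQ.4YTWqo4Qkkpue1KxY12riKLC91P8S3rn"
#> [5] "refseq:DEMO_1.1"

# and back again: the digest CURIE fetches the same sequence
sv_fetch(sv, "ga4gh:SQ.4YTWqo4Qkkpue1KxY12riKLC91P8S3rn")
#> [1] "GATTACAGATTACA"

# map-style access
p <- sv[["refseq:DEMO_1.1"]]
p
#> <sequence refseq:DEMO_1.1> 14 residues (4YTWqo4Qkkpue1KxY12riKLC91P8S3rn)
p[0, 4]
#> [1] "GATT"

sv_close(sv)
```

The five translated CURIEs are the four computed identifiers plus the
supplied accession; storing the same sequence again (under any case, and
any identifier) adds no sequence bytes — deduplication is by content.

## Command line

```sh
seqvault init /data/repo
seqvault load /data/repo -n refseq transcripts.fa.gz
seqvault status /data/repo
seqvault snapshot /data/repo /data/repo-2026-09-27   # hard links, incremental
seqvault serve /data/repo --port 8037
```

The executable lives at `inst/cli/seqvault` (on the installed package:
`system.file("cli", "seqvault", package = "seqvault")`). `serve` exposes
`GET /v1/sequence/{id}`, `GET /v1/metadata/{id}`, `GET /v1/ping`, and the
refget endpoints `GET /sequence/{digest}[/metadata]` and
`GET /sequence/service-info`, all read-only.

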