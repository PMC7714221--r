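---
title: "seqvault: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqvault: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput and clinical sequence-analysis pipelines need fast, local,
reproducible access to the reference sequences they validate and normalize
variants against. Remote accession services add network latency, rate
limits, and availability and privacy risks; local flat FASTA files are
redundant across providers and offer no identifier management. seqvault
maintains a local, non-redundant, content-addressed collection of
sequences of any species or molecule type, with fast random access to
slices and full identifier cross-referencing, so that conventional
accessions (`refseq:NM_000551.3`) and digest identifiers
(`ga4gh:SQ.<digest>`) are interchangeable keys into the same store.

## Content addressing: the sha512t24u digest

Every sequence is keyed internally by `sha512t24u(seq)`: the SHA-512
digest of the uppercased sequence bytes, truncated to its first 24 bytes
(192 bits) and encoded with unpadded URL-safe base64. The result is a
fixed 32-character string over `A-Z a-z 0-9 - _` that can be used directly
in URLs, FASTA headers and file names.

Three design points matter:

* **Truncation is a prefix.** The digest keeps the standard SHA-512
  initialization vector rather than the SHA-512/t parameterization, so a
  24-byte digest is a prefix of any longer truncation of the same input;
  abbreviated digests remain comparable.
* **Truncation length is modulo 3.** Base64 encodes 3 bytes into 4
  characters, so only multiples of 3 bytes encode without padding; 24
  bytes gives a 32-character key.
* **Collision risk is negligible at the chosen width.** Under the
  birthday bound, the probability that at least two of $n$ uniformly
  random $b$-bit digests collide is approximately
  $1 - \exp\!\left(-\,n(n-1)/2^{\,b+1}\right)$. `collision_probability()`
  evaluates the exact birthday product in log space for $n \le 10^6$ and
  this approximation (also in log space) above, so it stays finite and
  accurate out to $n = 10^{18}$, $b = 192$, where the probability is
  below $10^{-21}$. The exact branch exists because the approximation is
  visibly biased at tiny $n$ (for two messages and a one-bit digest the
  exact answer is $1/2$, the approximation $0.39$); the two branches
  agree to about $10^{-7}$ relative at the switch point, and both are
  monotone in each argument.

Alongside sha512t24u, every sequence gets three further computed
identifiers: hex MD5, hex SHA-1, and SEGUID (standard-alphabet base64 of
the SHA-1 of the uppercased sequence, padding stripped — 27 characters
that may contain `+` or `/`, which is the historical reason a URL-safe
convention was wanted).

**Case normalization.** Sequences are uppercased at a single point before
both hashing and storage, so `"acgt"` and `"ACGT"` deduplicate to one
record and one digest. FASTA case conventions (soft-masking) are thereby
deliberately erased; a pipeline that needs mask information must keep it
out of band. This is a declared package convention, documented here
because reasonable implementations could choose otherwise; SEGUID already
requires uppercasing, so the four computed identifiers stay mutually
consistent.

**Input alphabet.** Stored sequences must consist of residue characters
`A-Z a-z` plus `* . + -`. This covers the IUPAC nucleotide and amino-acid
codes, gap and stop symbols; digits and punctuation are rejected at
store time. Slices are read back through `Rsamtools::scanFa()` as
`AAStringSet`, whose alphabet is exactly this residue set.

## Storage layout

```
<root>/sequences/YYYY/MMDD/HHMMSS.fa.bgz      volume (BGZF FASTA)
<root>/sequences/YYYY/MMDD/HHMMSS.fa.bgz.fai  faidx index
<root>/sequences/YYYY/MMDD/HHMMSS.fa.bgz.gzi  BGZF virtual-offset index
<root>/sequences/db                           manifest (SQLite)
<root>/aliases/db                             alias database (SQLite)
```

Writes go to a plain-text staging FASTA (fixed 100-character lines, the
constant line width the faidx index requires). `sv_commit()` compresses
the staging file to BGZF with htslib (via Rsamtools), builds the `.fai`
and `.gzi` indexes, and registers the volume and all its sequence records
in the manifest inside one SQLite transaction. Volumes are named by UTC
second timestamp; a same-second collision gets a numeric suffix. A volume
is **immutable once finalized**: nothing ever rewrites or deletes its
bytes, which is what makes hard-link snapshots sound and lets mirrors
transfer only increments.

A volume closes per commit (one per load session). Size-based rollover
would be a straightforward extension but is not implemented; loads at the
scale this package targets produce comfortably sized volumes.

**Coordinates** are 0-based and half-open everywhere — the native
`sv_fetch(sv, id, start, end)`, the map-style proxy `sv[[id]][start, end]`,
and the HTTP `start`/`end` query parameters all share one convention, so
the four access routes return byte-identical slices by construction
rather than by translation. (An R user may expect 1-based closed
intervals; choosing the refget convention package-wide avoids two
coordinate systems in one code base, and is called out in every relevant
help page.)

**Concurrency contract.** Exactly one writer at a time (a lock file under
`sequences/` enforces this), any number of readers. Pending (uncommitted)
records live in writer memory and the staging file only; the manifest row
and the volume appear together at commit, so readers never observe a
partially written volume.

**Fetch performance.** A slice fetch resolves the identifier (two SQLite
point queries), then reads only the requested range through the
faidx/BGZF indexes — decompression work is proportional to the slice, not
the sequence. `GRanges` construction turned out to dominate the
per-call cost (milliseconds of S4 overhead per lookup), so the store
keeps a per-sequence range template and swaps in the requested interval;
median slice latency on a 300 kb sequence is a few milliseconds in the
test environment. The HTTP layer assembles each response body in memory,
so peak server memory is proportional to the largest requested slice;
truly chunked streaming is a known limitation.

## The alias database

Identifiers are `<namespace, alias>` pairs; their serialized form is the
CURIE `namespace:alias` (split at the *first* colon, so aliases may
contain colons). Namespaces follow identifiers.org lowercase prefixes
where such exist (`refseq`, `ensembl`); common alternative spellings are
canonicalized on input (`RefSeq` → `refseq`, `md5` → `MD5`). Alias
comparison is exact byte equality — no version stripping; a versionless
lookup is out of scope.

Rules, enforced in `sa_store_alias()`:

* An alias is unique within its namespace *at any point in time*.
* Re-asserting an existing pair with the same sequence is a no-op.
* Re-asserting it with a *different* sequence deprecates the old record
  (`is_current = 0`) and inserts a new current one. Records are never
  deleted and all carry UTC timestamps, so the naming history of any
  sequence — accession reassignments included — is queryable
  (`sa_find_aliases(..., current_only = FALSE)`). A pair later
  re-asserted with its original sequence inserts a third record rather
  than resurrecting the first: history is strictly append-only.
* The four computed namespaces (`MD5`, `SEGUID`, `SHA1`, `ga4gh`) can
  never be reassigned, since their alias is a pure function of the
  sequence; a conflicting assertion there indicates corruption and is
  refused outright.

The stored ga4gh record has alias `SQ.<sha512t24u>`; the bare spelling
`sha512t24u:<digest>` is accepted at query time and mapped onto that
record, so both resolve without storing a redundant fifth row. Bare
aliases (no namespace) resolve only when globally unique; if current
records in different namespaces point at different sequences the lookup
fails with the candidate CURIEs listed, rather than guessing by any
priority order — explicit over implicit.

## Snapshots

`sv_snapshot()` hard-links every finalized volume and its two index files
into the destination and copies only the two SQLite files (the sole
mutable artifacts). No sequence data is duplicated: link counts increment
and inodes are shared. Because volumes are append-only, a second snapshot
taken after further loads re-links all old volumes and materializes only
the new ones — successive snapshots cost disk space proportional to what
was added between them. Destinations must be on the same filesystem
(hard links cannot cross devices; the error message says to copy
instead) and must be absent or empty. A snapshot opens as an ordinary
read-only repository: it serves every read but refuses stores.

## HTTP surfaces

One httpuv application serves two read-only surfaces over the same open
repository; any method other than GET gets 405.

| surface | route | notes |
|---|---|---|
| native | `GET /v1/ping` | service info, sequence count |
| native | `GET /v1/sequence/{id}?start&end` | `id` is a CURIE or bare alias |
| native | `GET /v1/metadata/{id}` | length, alphabet, timestamp, alias CURIEs |
| refget | `GET /sequence/service-info` | `circular_supported: false` |
| refget | `GET /sequence/{digest}?start&end` | bare digests only |
| refget | `GET /sequence/{digest}/metadata` | md5, ga4gh, trunc512, aliases |

Error mapping: the native surface uses 404 (unknown), 422 (bad range, or
ambiguous bare alias with candidates in the body) and 400 (malformed
parameters); the refget surface uses 404, 416 (out of bounds) and 501
for `start > end`, which in refget denotes circular-sequence semantics —
not supported here (circular sequences can be stored linearized, but no
coordinate wrapping is provided). Range requests use query parameters
only; the refget `Range` header variant is a documented deviation from
full protocol compliance. Because refget's digest naming differs between
protocol generations (`trunc512` hex versus `ga4gh:SQ.` base64url — the
same 24 truncated bytes in two spellings), the server accepts a 48-char
hex digest, a 32-char base64url digest, or a 32-char hex MD5, and reports
all three in metadata.

## The synthetic-data generator

All tests run on generated input; nothing is downloaded. `fasta_spec()`
fixes record count, length range, alphabet, seed, a duplicate fraction
and an optional namespace alternation; generation selects the
Mersenne-Twister generator explicitly (restoring the caller's RNG state),
so one spec yields byte-identical FASTA on any platform. The duplicate
fraction makes the trailing `floor(f·n)` records repeat earlier
sequences under fresh identifiers — exactly the redundancy pattern that
store-level deduplication must collapse. `generate_conflict_set()` emits
two files sharing identifiers with guaranteed-divergent sequences
(disjoint length ranges), the minimal reproduction of an accession
reassignment.

The generator emulates record structure, not biology: residues are
i.i.d. uniform, so GC content, repeats and homopolymer structure of real
genomes are absent. Passing tests therefore demonstrate storage,
identity, history and interface correctness — which do not depend on
sequence composition — and say nothing about, e.g., compression ratios
on real genomes.

## Problem sizes and numerical choices

The shipped tests use: 100–200 random byte-strings per digest property;
a 1,000-record FASTA (40–200 bp) loaded twice for the deduplication and
immutability checks; 1,000 random (sequence, start, end) triples compared
byte-for-byte across the native call, the map proxy, `/v1` and refget
against a live local server; round trips up to 100 kb per sequence; and a
100-fetch latency sample on a 300 kb sequence with a 10 ms median bound.
These sizes exercise every code path (multi-line records, empty slices,
whole-sequence reads, same-second volume collisions) while keeping the
suite fast enough to run habitually.

Degenerate inputs are pinned down deliberately: the empty string hashes
(`sha512t24u("")` is defined) but is not storable; `fetch(id, k, k)`
returns the empty string for any valid `k`; a slice with `start > end` or
`end > length` is a range error distinct from not-found; non-ASCII or
non-residue input fails before anything is written.

## Known limitations

* No circular-sequence support (store linearized; no wraparound fetch).
* HTTP responses are assembled in memory rather than streamed.
* Single-writer design; no multi-writer coordination or authentication.
* Alias lookups are exact; no version-number awareness.
* One storage backend (BGZF volumes + SQLite); the module boundaries
  would admit others, but none are implemented.
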