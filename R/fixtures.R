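#' Specification for a seeded synthetic FASTA file
#'
#' Describes a reproducible synthetic sequence set: generation is a pure
#' function of the spec, so the same spec always produces byte-identical
#' FASTA output (the Mersenne-Twister generator is selected explicitly and
#' the caller's RNG state is restored afterwards). A
#' `duplicate_fraction` > 0 makes the last `floor(fraction * n)` records
#' repeat the sequence of an earlier record under a fresh identifier,
#' exercising store-level deduplication. `cross_namespace = TRUE`
#' alternates the suggested namespace between `nsA` and `nsB` in the
#' returned record table.
#'
#' @param n_records Number of records.
#' @param length_range Integer min/max sequence length.
#' @param alphabet Residue alphabet as a string, e.g. `"ACGT"` or the
#'   20 amino-acid letters; must be non-empty.
#' @param seed Integer seed.
#' @param duplicate_fraction Proportion in `[0, 1]` of records that repeat
#'   an earlier sequence.
#' @param cross_namespace Alternate namespaces in the record table?
#' @return A `fasta_spec` list.
#' @export
fasta_spec <- function(n_records = 10, length_range = c(50, 500),
                       alphabet = "ACGT", seed = 1,
                       duplicate_fraction = 0, cross_namespace = FALSE) {
  if (!is.character(alphabet) || length(alphabet) != 1L || !nzchar(alphabet)) {
    sv_usage("alphabet must be a non-empty string")
  }
  if (n_records < 1 || length_range[1] < 1 || length_range[2] < length_range[1] ||
      duplicate_fraction < 0 || duplicate_fraction > 1) {
    sv_usage("invalid synthetic FASTA specification")
  }
  structure(list(
    n_records = as.integer(n_records),
    length_range = as.integer(length_range),
    alphabet = alphabet,
    seed = as.integer(seed),
    duplicate_fraction = duplicate_fraction,
    cross_namespace = isTRUE(cross_namespace)
  ), class = "fasta_spec")
}

# run code under the spec's seed with a fixed RNG kind, restoring the
# caller's RNG state afterwards
with_spec_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

random_residues <- function(n, letters_vec) {
  paste(sample(letters_vec, n, replace = TRUE), collapse = "")
}

#' Generate the records of a synthetic FASTA set
#'
#' @param spec A [fasta_spec()].
#' @return A data.frame with columns `id`, `seq`, `namespace` and
#'   `is_duplicate` (does the record repeat an earlier sequence?).
#' @export
synthetic_records <- function(spec) {
  stopifnot(inherits(spec, "fasta_spec"))
  ab <- strsplit(spec$alphabet, "", fixed = TRUE)[[1]]
  n <- spec$n_records
  n_dup <- as.integer(floor(spec$duplicate_fraction * n))
  n_dup <- min(n_dup, n - 1L)   # need at least one original to copy
  with_spec_rng(spec$seed, {
    lens <- sample(seq.int(spec$length_range[1], spec$length_range[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, random_residues, "", letters_vec = ab)
    if (n_dup > 0L) {
      dup_slots <- seq.int(n - n_dup + 1L, n)
      sources <- sample(seq_len(n - n_dup), n_dup, replace = TRUE)
      seqs[dup_slots] <- seqs[sources]
    }
    data.frame(
      id = sprintf("SYN%06d", seq_len(n)),
      seq = seqs,
      namespace = if (spec$cross_namespace) {
        rep_len(c("nsA", "nsB"), n)
      } else {
        rep_len("nsA", n)
      },
      is_duplicate = seq_len(n) > (n - n_dup),
      stringsAsFactors = FALSE
    )
  })
}

#' Write a synthetic FASTA file
#'
#' Deterministic: the same spec yields byte-identical output (70-column
#' sequence lines, `\n` line endings).
#'
#' @param spec A [fasta_spec()].
#' @param path Output path.
#' @return The record table from [synthetic_records()], invisibly.
#' @export
write_synthetic_fasta <- function(spec, path) {
  recs <- synthetic_records(spec)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(recs))) {
    writeLines(paste0(">", recs$id[[i]]), con, sep = "\n", useBytes = TRUE)
    s <- recs$seq[[i]]
    starts <- seq.int(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con,
               sep = "\n", useBytes = TRUE)
  }
  invisible(recs)
}

#' Generate a pair of FASTA files exercising alias deprecation
#'
#' Both files carry the same record identifiers but divergent sequences
#' (lengths differ by one residue, so the content is guaranteed to
#' differ). Loading them in order into one namespace reassigns every
#' shared identifier, deprecating the first association of each.
#'
#' @param seed Integer seed.
#' @param dir Directory for the two files.
#' @param n_records Number of shared identifiers.
#' @return List with `file_a`, `file_b` and `ids`.
#' @export
generate_conflict_set <- function(seed, dir, n_records = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec_a <- fasta_spec(n_records = n_records, length_range = c(80, 120),
                       seed = seed)
  spec_b <- fasta_spec(n_records = n_records, length_range = c(121, 160),
                       seed = seed + 1L)
  file_a <- file.path(dir, "conflict_a.fa")
  file_b <- file.path(dir, "conflict_b.fa")
  recs_a <- write_synthetic_fasta(spec_a, file_a)
  recs_b <- write_synthetic_fasta(spec_b, file_b)
  stopifnot(identical(recs_a$id, recs_b$id))
  list(file_a = file_a, file_b = file_b, ids = recs_a$id)
}
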