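#' Create an empty sequence repository
#'
#' Lays out `<root>/sequences` (BGZF volume store + manifest) and
#' `<root>/aliases` (alias database). Refuses to touch an existing
#' non-empty target.
#'
#' @param root Repository root directory (absent, or an empty directory).
#' @return `root`, invisibly.
#' @export
seqvault_init <- function(root) {
  if (file.exists(root) && length(list.files(root, all.files = TRUE, no.. = TRUE)) > 0L) {
    sv_usage(sprintf("target '%s' already exists and is not empty", root))
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  fd <- fastadir(file.path(root, "sequences"), create = TRUE)
  fd_close(fd)
  sa <- seqaliasdb(file.path(root, "aliases"), create = TRUE)
  sa_close(sa)
  invisible(root)
}

#' Open a sequence repository
#'
#' The facade over the sequence store and the alias database: store
#' sequences together with their identifiers, fetch (slices of) sequences
#' by any current identifier, translate identifiers across namespaces, and
#' snapshot the repository. Instances open read-only by default; writes
#' require `writeable = TRUE` and are finalized with [sv_commit()].
#'
#' @param root Repository root created by [seqvault_init()].
#' @param writeable Open for writing?
#' @return A `seqvault` object.
#' @examples
#' root <- file.path(tempdir(), "sv-example")
#' seqvault_init(root)
#' sv <- seqvault(root, writeable = TRUE)
#' sv_store(sv, "ACGTACGT", "refseq:TEST0")
#' sv_commit(sv)
#' sv_fetch(sv, "refseq:TEST0", 2, 4)   # "GT"
#' sv_close(sv)
#' unlink(root, recursive = TRUE)
#' @export
seqvault <- function(root, writeable = FALSE) {
  if (!dir.exists(file.path(root, "sequences")) ||
      !dir.exists(file.path(root, "aliases"))) {
    sv_io_error(sprintf("'%s' is not a seqvault repository", root))
  }
  sv <- new.env(parent = emptyenv())
  sv$root <- normalizePath(root)
  sv$writeable <- writeable
  sv$fd <- fastadir(file.path(root, "sequences"), writeable = writeable)
  sv$sa <- seqaliasdb(file.path(root, "aliases"), writeable = writeable,
                      seq_exists = function(seq_id) fd_exists(sv$fd, seq_id))
  class(sv) <- "seqvault"
  sv
}

#' @export
print.seqvault <- function(x, ...) {
  st <- sv_stats(x)
  cat(sprintf("<seqvault> %s%s\n  %d sequences, %d current aliases, %.0f residues\n",
              x$root, if (x$writeable) " [writeable]" else " [read-only]",
              st$n_sequences, st$n_aliases, st$total_residues))
  invisible(x)
}

#' Store a sequence with its identifiers
#'
#' The sequence is deduplicated in the store; its four computed
#' identifiers (MD5, SEGUID, SHA1, `ga4gh:SQ.<sha512t24u>`) plus every
#' supplied CURIE are recorded in the alias database. Fully redundant
#' calls return zero counts. Identifiers are parsed before anything is
#' written, so a malformed CURIE leaves the repository untouched.
#'
#' @param sv A writeable [seqvault()].
#' @param seq Non-empty residue string.
#' @param identifiers Character vector of `namespace:alias` CURIEs
#'   (possibly empty).
#' @return List with `n_seqs_added`, `n_aliases_added` and
#'   `n_aliases_deprecated`.
#' @export
sv_store <- function(sv, seq, identifiers = character()) {
  if (!sv$writeable) sv_readonly("cannot store into a read-only repository")
  parsed <- lapply(identifiers, parse_curie)
  res <- fd_store(sv$fd, seq)
  ids <- compute_identifiers(seq)
  n_alias <- 0L
  n_depr <- 0L
  for (i in seq_len(nrow(ids))) {
    r <- sa_store_alias(sv$sa, res$seq_id, ids$namespace[[i]], ids$alias[[i]])
    n_alias <- n_alias + r$created
    n_depr <- n_depr + r$deprecated
  }
  for (p in parsed) {
    r <- sa_store_alias(sv$sa, res$seq_id, p$namespace, p$alias)
    n_alias <- n_alias + r$created
    n_depr <- n_depr + r$deprecated
  }
  list(n_seqs_added = as.integer(res$created),
       n_aliases_added = n_alias,
       n_aliases_deprecated = n_depr)
}

# resolve a CURIE or bare alias to exactly one internal key
sv_resolve <- function(sv, identifier) {
  p <- parse_identifier(identifier)
  ids <- sa_translate(sv$sa, p$alias,
                      namespace = if (is.na(p$namespace)) NULL else p$namespace)
  if (length(ids) == 0L) {
    sv_not_found(sprintf("identifier not found: %s", identifier))
  }
  ids[[1L]]
}

#' Fetch a sequence or slice by identifier
#'
#' The identifier may be a CURIE in any current namespace -- conventional
#' (`refseq:NM_...`) or digest-based (`ga4gh:SQ.<digest>`,
#' `sha512t24u:<digest>`, `MD5:<hex>`, ...) -- or a bare alias when it is
#' globally unique. Coordinates are 0-based, half-open.
#'
#' @param sv A [seqvault()].
#' @param identifier CURIE or bare alias.
#' @param start,end Optional slice bounds.
#' @return The (sub)sequence string.
#' @export
sv_fetch <- function(sv, identifier, start = NULL, end = NULL) {
  fd_fetch(sv$fd, sv_resolve(sv, identifier), start = start, end = end)
}

#' Translate an identifier into all current aliases of its sequence
#'
#' Resolves the identifier to a stored sequence and returns every current
#' alias of that sequence as a CURIE, in deterministic
#' (namespace, alias) order, optionally filtered to target namespaces.
#' This is the bridge in both directions between conventional accessions
#' and digest identifiers.
#'
#' @param sv A [seqvault()].
#' @param identifier CURIE or bare alias.
#' @param target_namespaces Optional character vector restricting the
#'   output namespaces (an empty vector yields an empty result). The
#'   special target `"sha512t24u"` emits the bare-digest spelling of the
#'   `ga4gh` record.
#' @return Character vector of CURIEs.
#' @export
sv_translate_identifier <- function(sv, identifier, target_namespaces = NULL) {
  seq_id <- sv_resolve(sv, identifier)
  df <- sa_find_aliases(sv$sa, seq_id = seq_id, current_only = TRUE)
  df <- df[order(df$namespace, df$alias, method = "radix"), , drop = FALSE]
  curies <- format_curie(df$namespace, df$alias)
  if (is.null(target_namespaces)) {
    return(curies)
  }
  targets <- vapply(target_namespaces, normalize_namespace, "")
  out <- curies[df$namespace %in% targets]
  if ("sha512t24u" %in% target_namespaces) {
    ga <- df$alias[df$namespace == "ga4gh"]
    out <- c(out, paste0("sha512t24u:", sub("^SQ\\.", "", ga)))
  }
  sort(out, method = "radix")
}

#' @rdname sv_translate_identifier
#' @details `sv_contains()` mirrors translation success: `TRUE` exactly
#'   when the identifier resolves to one stored sequence.
#' @export
sv_contains <- function(sv, identifier) {
  tryCatch({
    sv_resolve(sv, identifier)
    TRUE
  }, seqvault_error = function(e) FALSE)
}

#' Repository inventory
#'
#' `sv_list_ids()` returns each internal sequence key exactly once;
#' `sv_stats()` returns record counts consistent with the stores.
#'
#' @param sv A [seqvault()].
#' @return `sv_list_ids()`: character vector of digests. `sv_stats()`:
#'   list with `n_sequences`, `n_aliases` (current), `total_residues`.
#' @export
sv_list_ids <- function(sv) {
  fd_seq_ids(sv$fd)
}

#' @rdname sv_list_ids
#' @export
sv_stats <- function(sv) {
  st <- fd_stats(sv$fd)
  list(n_sequences = st$n_sequences,
       n_aliases = sa_count(sv$sa, current_only = TRUE),
       total_residues = st$total_residues)
}

#' @rdname sv_store
#' @details `sv_commit()` finalizes the current BGZF volume (see
#'   [fd_commit()]).
#' @export
sv_commit <- function(sv) {
  fd_commit(sv$fd)
  invisible(sv)
}

#' Metadata for an identifier
#'
#' @param sv A [seqvault()].
#' @param identifier CURIE or bare alias.
#' @return List with `added`, `length`, `alphabet` and `aliases` (sorted
#'   current CURIEs).
#' @export
sv_metadata <- function(sv, identifier) {
  seq_id <- sv_resolve(sv, identifier)
  info <- fd_info(sv$fd, seq_id)
  list(added = info$added,
       length = info$len,
       alphabet = info$alpha,
       aliases = sv_translate_identifier(sv, identifier))
}

#' Snapshot a repository with hard links
#'
#' Creates a read-only copy at `dest`: every finalized volume file and its
#' indexes is hard-linked (no sequence data is copied, link counts
#' increment), and only the two small database files are copied, since
#' they are the sole mutable artifacts. Because volumes are immutable and
#' append-only, a later snapshot after k new sequences re-links all old
#' volumes and materializes only the new ones -- snapshots are incremental
#' in disk usage. Pending writes are committed first on a writeable
#' instance.
#'
#' @param sv A [seqvault()].
#' @param dest Destination directory on the same filesystem; absent or
#'   empty.
#' @return List with `n_files_linked` and `n_files_copied`.
#' @export
sv_snapshot <- function(sv, dest) {
  if (file.exists(dest) && length(list.files(dest, all.files = TRUE, no.. = TRUE)) > 0L) {
    sv_usage(sprintf("snapshot destination '%s' is not empty", dest))
  }
  if (sv$writeable) sv_commit(sv)
  dir.create(file.path(dest, "sequences"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dest, "aliases"), recursive = TRUE, showWarnings = FALSE)
  vols <- fd_volumes(sv$fd)$relpath
  n_linked <- 0L
  for (rel in vols) {
    for (suffix in c("", ".fai", ".gzi")) {
      src <- file.path(sv$root, "sequences", paste0(rel, suffix))
      if (!file.exists(src)) next
      dst <- file.path(dest, "sequences", paste0(rel, suffix))
      dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
      ok <- suppressWarnings(file.link(src, dst))
      if (!ok) {
        sv_io_error(sprintf(
          "cannot hard-link '%s' to '%s' (cross-device destination? copy the tree instead)",
          src, dst))
      }
      n_linked <- n_linked + 1L
    }
  }
  file.copy(file.path(sv$root, "sequences", "db"), file.path(dest, "sequences", "db"))
  file.copy(file.path(sv$root, "aliases", "db"), file.path(dest, "aliases", "db"))
  list(n_files_linked = n_linked, n_files_copied = 2L)
}

#' @rdname seqvault
#' @param sv A [seqvault()] to close.
#' @export
sv_close <- function(sv) {
  fd_close(sv$fd)
  sa_close(sv$sa)
  invisible(NULL)
}

# --- map-style access -----------------------------------------------------

#' Map-style access to stored sequences
#'
#' `sv[["refseq:TEST0"]]` returns a lazy sequence proxy;
#' `proxy[start, end]` fetches the 0-based half-open slice (the identical
#' contract as [sv_fetch()]), `proxy[]` or `as.character(proxy)` the full
#' sequence, and `length(proxy)` the sequence length. Resolution happens
#' eagerly, so an unknown identifier fails at subscript time.
#'
#' @param x A [seqvault()] (or a proxy, for the slice operator).
#' @param i Identifier string; for the proxy, the 0-based slice start.
#' @param j For the proxy, the half-open slice end.
#' @return A `seqvault_proxy`, or a character slice.
#' @rdname seqvault_proxy
#' @export
`[[.seqvault` <- function(x, i) {
  seq_id <- sv_resolve(x, i)
  structure(list(sv = x, identifier = i, seq_id = seq_id),
            class = "seqvault_proxy")
}

#' @rdname seqvault_proxy
#' @export
`[.seqvault_proxy` <- function(x, i, j) {
  start <- if (missing(i)) NULL else i
  end <- if (missing(j)) NULL else j
  fd_fetch(x$sv$fd, x$seq_id, start = start, end = end)
}

#' @rdname seqvault_proxy
#' @export
as.character.seqvault_proxy <- function(x, ...) {
  fd_fetch(x$sv$fd, x$seq_id)
}

#' @rdname seqvault_proxy
#' @export
length.seqvault_proxy <- function(x) {
  fd_info(x$sv$fd, x$seq_id)$len
}

#' @export
print.seqvault_proxy <- function(x, ...) {
  info <- fd_info(x$sv$fd, x$seq_id)
  cat(sprintf("<sequence %s> %d residues (%s)\n", x$identifier, info$len, x$seq_id))
  invisible(x)
}
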