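#' Load a FASTA file into a repository
#'
#' Each record is stored via [sv_store()] under the identifier
#' `namespace:<first whitespace-delimited defline token>`; the rest of the
#' defline is ignored. Plain, gzip- and bgzip-compressed input are all
#' accepted (detected by content, not extension). One [sv_commit()] after
#' the last record finalizes a single volume per call.
#'
#' Duplicate identifiers within a file pointing at different sequences are
#' processed under the alias-conflict rules (the earlier association is
#' deprecated) and counted in the report.
#'
#' @param sv A writeable [seqvault()].
#' @param path FASTA file.
#' @param namespace Namespace for the file's identifiers.
#' @return List with `n_seen`, `n_seqs_added`, `n_aliases_added`,
#'   `n_aliases_deprecated`.
#' @export
sv_load_fasta <- function(sv, path, namespace) {
  if (!file.exists(path)) {
    sv_io_error(sprintf("no such file: '%s'", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      sv_io_error(sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)))
    })
  ids <- sub("\\s.*$", "", names(set))
  report <- list(n_seen = length(set), n_seqs_added = 0L,
                 n_aliases_added = 0L, n_aliases_deprecated = 0L)
  for (i in seq_along(set)) {
    if (!nzchar(ids[[i]])) {
      sv_io_error(sprintf("malformed FASTA in '%s': record %d has an empty identifier",
                          path, i))
    }
    r <- sv_store(sv, as.character(set[[i]]),
                  identifiers = format_curie(namespace, ids[[i]]))
    report$n_seqs_added <- report$n_seqs_added + r$n_seqs_added
    report$n_aliases_added <- report$n_aliases_added + r$n_aliases_added
    report$n_aliases_deprecated <- report$n_aliases_deprecated + r$n_aliases_deprecated
  }
  sv_commit(sv)
  report
}

#' Export a repository as FASTA
#'
#' Writes every stored sequence with its internal digest key as the FASTA
#' identifier and its current alias CURIEs as the defline comment, so an
#' export/load round trip into a fresh repository preserves the set of
#' sequence keys exactly.
#'
#' @param sv A [seqvault()].
#' @param path Output file, or `""` for standard output.
#' @param namespace Optional filter: only sequences having a current alias
#'   in this namespace are exported.
#' @return Number of records written, invisibly.
#' @export
sv_export_fasta <- function(sv, path = "", namespace = NULL) {
  con <- if (nzchar(path)) file(path, open = "w") else stdout()
  if (nzchar(path)) on.exit(close(con), add = TRUE)
  n <- 0L
  for (seq_id in sv_list_ids(sv)) {
    aliases <- sa_find_aliases(sv$sa, seq_id = seq_id, current_only = TRUE)
    if (!is.null(namespace) &&
        !(normalize_namespace(namespace) %in% aliases$namespace)) {
      next
    }
    aliases <- aliases[order(aliases$namespace, aliases$alias, method = "radix"), , drop = FALSE]
    writeLines(paste0(">", seq_id, " ",
                      paste(format_curie(aliases$namespace, aliases$alias),
                            collapse = " ")), con)
    s <- fd_fetch(sv$fd, seq_id)
    starts <- seq.int(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
    n <- n + 1L
  }
  invisible(n)
}
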