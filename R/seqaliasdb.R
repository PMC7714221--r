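#' Open or create a sequence alias database
#'
#' Stores timestamped `<namespace, alias>` associations onto internal
#' sequence keys in a single-file SQLite database. Aliases are unique
#' within a namespace at any point in time: re-asserting an existing pair
#' with the same sequence is a no-op, while re-asserting it with a
#' different sequence deprecates the old record (`is_current = 0`) and
#' inserts a new current one, preserving the full naming history. Records
#' are never deleted.
#'
#' @param dir Directory of the database (conventionally `<root>/aliases`).
#' @param writeable Open for writing?
#' @param create Create a new database (implies `writeable`).
#' @param seq_exists Optional function `(seq_id) -> logical` used to
#'   enforce referential integrity against the sequence store; when `NULL`
#'   no check is performed.
#' @return A `seqaliasdb` object.
#' @export
seqaliasdb <- function(dir, writeable = FALSE, create = FALSE, seq_exists = NULL) {
  if (create) writeable <- TRUE
  dbpath <- file.path(dir, "db")
  if (!create && !file.exists(dbpath)) {
    sv_io_error(sprintf("'%s' is not an alias database (no db file)", dir))
  }
  if (create) {
    if (file.exists(dbpath)) {
      sv_usage(sprintf("alias database already exists at '%s'", dir))
    }
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  sa <- new.env(parent = emptyenv())
  sa$dir <- normalizePath(dir)
  sa$writeable <- writeable
  sa$db <- DBI::dbConnect(RSQLite::SQLite(), dbpath)
  sa$seq_exists <- seq_exists
  class(sa) <- "seqaliasdb"
  if (create) {
    DBI::dbExecute(sa$db, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
    DBI::dbExecute(sa$db, "INSERT INTO meta VALUES ('schema_version', '1')")
    DBI::dbExecute(sa$db, paste(
      "CREATE TABLE seqalias (",
      " alias_id INTEGER PRIMARY KEY AUTOINCREMENT,",
      " seq_id TEXT NOT NULL, namespace TEXT NOT NULL, alias TEXT NOT NULL,",
      " added TEXT NOT NULL, is_current INTEGER NOT NULL DEFAULT 1)"))
    DBI::dbExecute(sa$db,
      "CREATE INDEX idx_ns_alias ON seqalias (namespace, alias)")
    DBI::dbExecute(sa$db, "CREATE INDEX idx_seq_id ON seqalias (seq_id)")
    DBI::dbExecute(sa$db, "CREATE INDEX idx_alias ON seqalias (alias)")
  }
  sa
}

#' @export
print.seqaliasdb <- function(x, ...) {
  n <- DBI::dbGetQuery(x$db, "SELECT COUNT(*) AS n FROM seqalias")$n
  cur <- DBI::dbGetQuery(x$db,
    "SELECT COUNT(*) AS n FROM seqalias WHERE is_current = 1")$n
  cat(sprintf("<seqaliasdb> %s\n  %d records (%d current)\n", x$dir, n, cur))
  invisible(x)
}

#' Associate an alias with a sequence
#'
#' Behaviour on an existing `<namespace, alias>` pair: pointing at the same
#' sequence, a no-op; pointing at a different sequence, the old record is
#' deprecated and a new current record inserted. Computed-identifier
#' namespaces (`MD5`, `SEGUID`, `SHA1`, `ga4gh`) can never be reassigned,
#' since their alias is a pure function of the sequence -- a conflicting
#' assertion there signals corruption and is refused.
#'
#' @param sa A writeable [seqaliasdb()].
#' @param seq_id Internal sequence key (must exist in the sequence store
#'   when the database was opened with a `seq_exists` check).
#' @param namespace,alias Non-empty strings; the namespace is
#'   canonicalized (`RefSeq` -> `refseq`, ...).
#' @return List with `alias_id`, `created` (new record inserted?) and
#'   `deprecated` (old record deprecated?).
#' @export
sa_store_alias <- function(sa, seq_id, namespace, alias) {
  if (!sa$writeable) sv_readonly("cannot store into a read-only alias database")
  namespace <- normalize_namespace(namespace)
  if (!is.character(alias) || length(alias) != 1L || is.na(alias) || !nzchar(alias)) {
    sv_usage("alias must be a non-empty string")
  }
  if (!is.null(sa$seq_exists) && !sa$seq_exists(seq_id)) {
    sv_referential(sprintf("unknown sequence id: %s", seq_id))
  }
  cur <- DBI::dbGetQuery(sa$db, paste(
    "SELECT alias_id, seq_id FROM seqalias",
    "WHERE namespace = :n AND alias = :a AND is_current = 1"),
    params = list(n = namespace, a = alias))
  if (nrow(cur) > 0L) {
    if (cur$seq_id[[1L]] == seq_id) {
      return(list(alias_id = cur$alias_id[[1L]], created = FALSE, deprecated = FALSE))
    }
    if (namespace %in% .computed_namespaces) {
      sv_referential(sprintf(
        "computed identifier %s:%s already maps to a different sequence",
        namespace, alias))
    }
    DBI::dbExecute(sa$db,
      "UPDATE seqalias SET is_current = 0 WHERE alias_id = :i",
      params = list(i = cur$alias_id[[1L]]))
    deprecated <- TRUE
  } else {
    deprecated <- FALSE
  }
  DBI::dbExecute(sa$db, paste(
    "INSERT INTO seqalias (seq_id, namespace, alias, added, is_current)",
    "VALUES (:s, :n, :a, :t, 1)"),
    params = list(s = seq_id, n = namespace, a = alias, t = utc_now()))
  id <- DBI::dbGetQuery(sa$db, "SELECT last_insert_rowid() AS i")$i
  list(alias_id = id, created = TRUE, deprecated = deprecated)
}

#' Query alias records
#'
#' At least one filter must be given. With `current_only = FALSE` the full
#' history is returned, ordered by insertion (deprecated records retain
#' their timestamps).
#'
#' @param sa A [seqaliasdb()].
#' @param namespace,alias,seq_id Optional filters, combined with AND.
#' @param current_only Restrict to current associations (default).
#' @return A data.frame with columns `alias_id`, `seq_id`, `namespace`,
#'   `alias`, `added`, `is_current`.
#' @export
sa_find_aliases <- function(sa, namespace = NULL, alias = NULL, seq_id = NULL,
                            current_only = TRUE) {
  if (is.null(namespace) && is.null(alias) && is.null(seq_id)) {
    sv_usage("at least one of namespace, alias, seq_id must be given")
  }
  where <- character()
  params <- list()
  if (!is.null(namespace)) {
    where <- c(where, "namespace = :n")
    params$n <- normalize_namespace(namespace)
  }
  if (!is.null(alias)) {
    where <- c(where, "alias = :a")
    params$a <- alias
  }
  if (!is.null(seq_id)) {
    where <- c(where, "seq_id = :s")
    params$s <- seq_id
  }
  if (current_only) where <- c(where, "is_current = 1")
  df <- DBI::dbGetQuery(sa$db, paste(
    "SELECT alias_id, seq_id, namespace, alias, added, is_current FROM seqalias",
    "WHERE", paste(where, collapse = " AND "),
    "ORDER BY added, alias_id"), params = params)
  df$is_current <- as.logical(df$is_current)
  df
}

#' Resolve an alias to internal sequence keys
#'
#' With a namespace, returns the key of the current record for that pair
#' (zero or one). Without one, the alias is looked up across all
#' namespaces and must be globally unique: if current records in different
#' namespaces point at different sequences, an ambiguity error naming the
#' candidate namespaces is raised.
#'
#' @param sa A [seqaliasdb()].
#' @param alias Alias string.
#' @param namespace Optional namespace.
#' @return Character vector of sequence keys (length 0 or 1).
#' @export
sa_translate <- function(sa, alias, namespace = NULL) {
  if (!is.character(alias) || length(alias) != 1L || is.na(alias) || !nzchar(alias)) {
    sv_usage("alias must be a non-empty string")
  }
  if (!is.null(namespace)) {
    q <- canonical_query(normalize_namespace(namespace), alias)
    df <- DBI::dbGetQuery(sa$db, paste(
      "SELECT DISTINCT seq_id FROM seqalias",
      "WHERE namespace = :n AND alias = :a AND is_current = 1"),
      params = list(n = q$namespace, a = q$alias))
    return(df$seq_id)
  }
  df <- DBI::dbGetQuery(sa$db, paste(
    "SELECT namespace, seq_id FROM seqalias",
    "WHERE alias = :a AND is_current = 1"), params = list(a = alias))
  ids <- unique(df$seq_id)
  if (length(ids) > 1L) {
    sv_ambiguous(
      sprintf("alias '%s' is ambiguous across namespaces: %s",
              alias, paste(sort(df$namespace), collapse = ", ")),
      candidates = format_curie(df$namespace, alias))
  }
  ids
}

#' Count alias records
#'
#' @param sa A [seqaliasdb()].
#' @param current_only Count only current associations?
#' @return Integer record count.
#' @export
sa_count <- function(sa, current_only = FALSE) {
  sql <- "SELECT COUNT(*) AS n FROM seqalias"
  if (current_only) sql <- paste(sql, "WHERE is_current = 1")
  DBI::dbGetQuery(sa$db, sql)$n
}

#' @rdname seqaliasdb
#' @param sa A [seqaliasdb()] to close.
#' @export
sa_close <- function(sa) {
  if (DBI::dbIsValid(sa$db)) DBI::dbDisconnect(sa$db)
  invisible(NULL)
}
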