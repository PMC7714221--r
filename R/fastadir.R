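#' Open or create a BGZF FASTA sequence store
#'
#' A fastadir stores sequences non-redundantly, keyed by their sha512t24u
#' digest, in append-only BGZF-compressed FASTA volume files. A SQLite
#' manifest records, per sequence, its length, alphabet (the sorted set of
#' distinct residues observed), load timestamp and volume path, plus the
#' registry of volumes. Volumes are named by UTC timestamp
#' (`YYYY/MMDD/HHMMSS.fa.bgz`) and are immutable once finalized: writes
#' during a session go to a plain-text staging file that [fd_commit()]
#' compresses, indexes (faidx `.fai` + BGZF `.gzi`) and registers. Slice
#' reads use the indexes, so fetching a range never decompresses the whole
#' sequence.
#'
#' @param dir Directory of the store (conventionally `<root>/sequences`).
#' @param writeable Open for writing? At most one writer at a time; any
#'   number of read-only instances may be open concurrently.
#' @param create Create a new store in `dir` (implies `writeable`).
#' @return A `fastadir` object (an environment with reference semantics).
#' @seealso [fd_store()], [fd_fetch()], [fd_info()], [fd_commit()]
#' @export
fastadir <- function(dir, writeable = FALSE, create = FALSE) {
  if (create) writeable <- TRUE
  dbpath <- file.path(dir, "db")
  if (!create && !file.exists(dbpath)) {
    sv_io_error(sprintf("'%s' is not a sequence store (no manifest db)", dir))
  }
  if (create) {
    if (file.exists(dbpath)) {
      sv_usage(sprintf("sequence store already exists at '%s'", dir))
    }
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  fd <- new.env(parent = emptyenv())
  fd$dir <- normalizePath(dir)
  fd$writeable <- writeable
  fd$db <- DBI::dbConnect(RSQLite::SQLite(), dbpath)
  fd$pending <- new.env(parent = emptyenv())  # seq_id -> record list
  fd$pending_order <- character()
  fd$session_relpath <- NULL
  fd$staging <- file.path(fd$dir, ".staging.fa")
  fd$staging_con <- NULL
  fd$fafiles <- new.env(parent = emptyenv())  # relpath -> open FaFile
  fd$granges <- new.env(parent = emptyenv())  # seq_id -> GRanges template
  class(fd) <- "fastadir"
  if (create) {
    DBI::dbExecute(fd$db, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
    DBI::dbExecute(fd$db, "INSERT INTO meta VALUES ('schema_version', '1')")
    DBI::dbExecute(fd$db, paste(
      "CREATE TABLE seqinfo (",
      " seq_id TEXT PRIMARY KEY, len INTEGER NOT NULL, alpha TEXT NOT NULL,",
      " added TEXT NOT NULL, relpath TEXT NOT NULL)"))
    DBI::dbExecute(fd$db, paste(
      "CREATE TABLE volumes (",
      " relpath TEXT PRIMARY KEY, created TEXT NOT NULL,",
      " finalized INTEGER NOT NULL DEFAULT 0)"))
  }
  if (writeable) {
    lock <- file.path(fd$dir, ".lock")
    if (file.exists(lock)) {
      DBI::dbDisconnect(fd$db)
      sv_usage(sprintf("another writer holds the lock on '%s'", dir))
    }
    writeLines(as.character(Sys.getpid()), lock)
    fd$lock <- lock
  }
  fd
}

#' @export
print.fastadir <- function(x, ...) {
  st <- fd_stats(x)
  cat(sprintf("<fastadir> %s\n  %d sequences, %.0f residues, %d volume(s)%s\n",
              x$dir, st$n_sequences, st$total_residues, st$n_volumes,
              if (x$writeable) " [writeable]" else " [read-only]"))
  invisible(x)
}

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# timestamped volume path; same-second collisions get a numeric suffix
new_volume_relpath <- function(fd) {
  base <- format(Sys.time(), "%Y/%m%d/%H%M%S", tz = "UTC")
  known <- DBI::dbGetQuery(fd$db, "SELECT relpath FROM volumes")$relpath
  rel <- paste0(base, ".fa.bgz")
  i <- 1L
  while (rel %in% known || file.exists(file.path(fd$dir, rel))) {
    i <- i + 1L
    rel <- sprintf("%s-%d.fa.bgz", base, i)
  }
  rel
}

#' Store one sequence
#'
#' The sequence is uppercased, hashed with [sha512t24u()], and appended to
#' the current open volume under its digest as FASTA identifier -- unless
#' that digest is already known, in which case nothing is written.
#' Idempotent under repetition.
#'
#' @param fd A writeable [fastadir()].
#' @param seq Non-empty sequence over residue characters `A-Z a-z * . + -`.
#' @return List with `seq_id` (the digest) and `created` (logical; `FALSE`
#'   when the sequence was already stored).
#' @export
fd_store <- function(fd, seq) {
  if (!fd$writeable) sv_readonly("cannot store into a read-only sequence store")
  seq <- normalize_sequence(seq)
  seq_id <- sha512t24u(seq)
  if (fd_exists(fd, seq_id)) {
    return(list(seq_id = seq_id, created = FALSE))
  }
  if (is.null(fd$session_relpath)) {
    fd$session_relpath <- new_volume_relpath(fd)
    fd$session_created <- utc_now()
    fd$staging_con <- file(fd$staging, open = "w")
  }
  writeLines(paste0(">", seq_id), fd$staging_con)
  starts <- seq.int(1L, nchar(seq), by = 100L)
  writeLines(substring(seq, starts, pmin(starts + 99L, nchar(seq))), fd$staging_con)
  fd$pending[[seq_id]] <- list(
    seq_id = seq_id,
    seq = seq,
    len = nchar(seq),
    alpha = paste(sort(unique(strsplit(seq, "", fixed = TRUE)[[1]])), collapse = ""),
    added = utc_now(),
    relpath = fd$session_relpath
  )
  fd$pending_order <- c(fd$pending_order, seq_id)
  list(seq_id = seq_id, created = TRUE)
}

#' Finalize the current volume
#'
#' BGZF-compresses the staging file into its timestamped volume, builds the
#' faidx and BGZF indexes, and registers the volume plus all pending
#' sequence records in the manifest in one transaction. Subsequent stores
#' open a new volume. A commit with no pending writes is a no-op. Readers
#' only ever observe finalized volumes with fully flushed manifest rows.
#'
#' @param fd A writeable [fastadir()].
#' @return The store, invisibly.
#' @export
fd_commit <- function(fd) {
  if (!fd$writeable) sv_readonly("cannot commit a read-only sequence store")
  if (is.null(fd$session_relpath)) return(invisible(fd))
  close(fd$staging_con)
  fd$staging_con <- NULL
  dest <- file.path(fd$dir, fd$session_relpath)
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  Rsamtools::bgzip(fd$staging, dest = dest, overwrite = FALSE)
  Rsamtools::indexFa(dest)
  DBI::dbWithTransaction(fd$db, {
    DBI::dbExecute(fd$db,
      "INSERT INTO volumes (relpath, created, finalized) VALUES (:r, :c, 1)",
      params = list(r = fd$session_relpath, c = fd$session_created))
    for (sid in fd$pending_order) {
      rec <- fd$pending[[sid]]
      DBI::dbExecute(fd$db, paste(
        "INSERT INTO seqinfo (seq_id, len, alpha, added, relpath)",
        "VALUES (:s, :l, :a, :t, :r)"),
        params = list(s = rec$seq_id, l = rec$len, a = rec$alpha,
                      t = rec$added, r = rec$relpath))
    }
  })
  file.remove(fd$staging)
  fd$pending <- new.env(parent = emptyenv())
  fd$pending_order <- character()
  fd$session_relpath <- NULL
  invisible(fd)
}

fd_exists <- function(fd, seq_id) {
  if (!is.null(fd$pending[[seq_id]])) return(TRUE)
  n <- DBI::dbGetQuery(fd$db,
    "SELECT COUNT(*) AS n FROM seqinfo WHERE seq_id = :s",
    params = list(s = seq_id))$n
  n > 0L
}

fd_record <- function(fd, seq_id) {
  rec <- fd$pending[[seq_id]]
  if (!is.null(rec)) return(rec)
  df <- DBI::dbGetQuery(fd$db,
    "SELECT seq_id, len, alpha, added, relpath FROM seqinfo WHERE seq_id = :s",
    params = list(s = seq_id))
  if (nrow(df) == 0L) {
    sv_not_found(sprintf("unknown sequence id: %s", seq_id))
  }
  as.list(df[1L, ])
}

#' Sequence metadata
#'
#' @param fd A [fastadir()].
#' @param seq_id Internal digest key.
#' @return List with `seq_id`, `len`, `alpha` (sorted distinct residues),
#'   `added` (UTC timestamp) and `relpath` (volume file relative to the
#'   store directory).
#' @export
fd_info <- function(fd, seq_id) {
  rec <- fd_record(fd, seq_id)
  rec[c("seq_id", "len", "alpha", "added", "relpath")]
}

# open (and cache) the FaFile handle for a finalized volume
fd_fafile <- function(fd, relpath) {
  fa <- fd$fafiles[[relpath]]
  if (is.null(fa)) {
    path <- file.path(fd$dir, relpath)
    fa <- Rsamtools::FaFile(path)
    open(fa)
    fd$fafiles[[relpath]] <- fa
  }
  fa
}

#' Fetch a sequence or slice by internal key
#'
#' Coordinates are 0-based and half-open, the package-wide convention
#' shared with the REST query parameters: `fetch(fd, id, a, b)` returns
#' residues `a .. b-1`. Omitted bounds default to the whole sequence.
#' Slices of finalized volumes are read through the faidx/BGZF indexes, so
#' only the requested range is decompressed.
#'
#' @param fd A [fastadir()].
#' @param seq_id Internal digest key.
#' @param start,end Optional slice bounds (0-based, half-open).
#' @return The (sub)sequence as a character string.
#' @export
fd_fetch <- function(fd, seq_id, start = NULL, end = NULL) {
  rec <- fd_record(fd, seq_id)
  len <- rec$len
  start <- check_bound(start, 0)
  end <- check_bound(end, len)
  if (start > end) {
    sv_range_error(sprintf("start (%d) greater than end (%d)", start, end))
  }
  if (end > len) {
    sv_range_error(sprintf("end (%d) beyond sequence length (%d)", end, len))
  }
  if (start == end) return("")
  if (!is.null(rec[["seq"]])) {                 # pending, not yet on disk
    return(substr(rec[["seq"]], start + 1L, end))
  }
  fa <- fd_fafile(fd, rec$relpath)
  # GRanges construction costs milliseconds; keep one template per
  # sequence and swap in the requested range so repeated slice fetches
  # stay fast
  gr <- fd$granges[[seq_id]]
  if (is.null(gr)) {
    gr <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(1, 1))
    fd$granges[[seq_id]] <- gr
  }
  gr@ranges <- IRanges::IRanges(start + 1, end)
  fd$granges[[seq_id]] <- gr
  unname(as.character(Rsamtools::scanFa(fa, param = gr, as = "AAStringSet")))
}

check_bound <- function(x, default) {
  if (is.null(x)) return(as.double(default))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x)) {
    sv_range_error("slice bounds must be single non-negative integers")
  }
  if (x < 0) sv_range_error("slice bounds must be non-negative")
  as.double(x)
}

#' @rdname fd_info
#' @export
fd_seq_ids <- function(fd) {
  c(DBI::dbGetQuery(fd$db, "SELECT seq_id FROM seqinfo ORDER BY rowid")$seq_id,
    fd$pending_order)
}

#' Store-level statistics and volume registry
#'
#' `fd_stats()` counts sequences, residues and volumes (including the
#' pending session); `fd_volumes()` lists finalized volumes oldest first.
#'
#' @param fd A [fastadir()].
#' @return `fd_stats()`: list with `n_sequences`, `total_residues`,
#'   `n_volumes`. `fd_volumes()`: data.frame with `relpath`, `created`,
#'   `finalized`.
#' @export
fd_stats <- function(fd) {
  df <- DBI::dbGetQuery(fd$db,
    "SELECT COUNT(*) AS n, COALESCE(SUM(len), 0) AS resid FROM seqinfo")
  nv <- DBI::dbGetQuery(fd$db, "SELECT COUNT(*) AS n FROM volumes")$n
  pend_len <- sum(vapply(fd$pending_order, function(s) fd$pending[[s]]$len, 0L))
  list(
    n_sequences = df$n + length(fd$pending_order),
    total_residues = df$resid + pend_len,
    n_volumes = nv + as.integer(!is.null(fd$session_relpath))
  )
}

#' @rdname fd_stats
#' @export
fd_volumes <- function(fd) {
  DBI::dbGetQuery(fd$db,
    "SELECT relpath, created, finalized FROM volumes ORDER BY rowid")
}

#' @rdname fastadir
#' @param fd A [fastadir()] to close.
#' @export
fd_close <- function(fd) {
  if (!is.null(fd$staging_con)) {
    close(fd$staging_con)
    fd$staging_con <- NULL
  }
  for (rp in ls(fd$fafiles)) {
    try(close(fd$fafiles[[rp]]), silent = TRUE)
  }
  fd$fafiles <- new.env(parent = emptyenv())
  if (DBI::dbIsValid(fd$db)) DBI::dbDisconnect(fd$db)
  if (!is.null(fd$lock) && file.exists(fd$lock)) file.remove(fd$lock)
  invisible(NULL)
}
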