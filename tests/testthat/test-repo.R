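# Repository facade: store-with-identifiers counts, fetch by any CURIE,
# identifier translation, map-style access, snapshots, read-only safety.

test_that("store records the four computed identifiers plus supplied CURIEs", {
  sv <- local_repo()
  r <- sv_store(sv, "ACGTACGT", "refseq:TEST0")
  expect_identical(r$n_seqs_added, 1L)
  expect_identical(r$n_aliases_added, 5L)
  r <- sv_store(sv, "ACGTACGT", "refseq:TEST0")
  expect_identical(r$n_seqs_added, 0L)
  expect_identical(r$n_aliases_added, 0L)
  r <- sv_store(sv, "ACGTACGT", "ensembl:ENST0")
  expect_identical(r$n_seqs_added, 0L)
  expect_identical(r$n_aliases_added, 1L)
  st <- sv_stats(sv)
  expect_identical(st$n_sequences, 1L)
  expect_identical(st$n_aliases, 6L)
  expect_identical(st$total_residues, 8L)
  # malformed CURIE is rejected before anything is written
  expect_error(sv_store(sv, "GGGG", ":broken"), class = "sv_parse_error")
  expect_identical(sv_stats(sv)$n_sequences, 1L)
})

test_that("every computed-identifier CURIE fetches the identical sequence", {
  sv <- local_repo()
  set.seed(31)
  seqs <- vapply(c(40, 123, 999), rand_seq, "")
  for (s in seqs) sv_store(sv, s, sprintf("custom:S%d", nchar(s)))
  sv_commit(sv)
  for (s in seqs) {
    curies <- sv_translate_identifier(sv, paste0("custom:S", nchar(s)))
    expect_gte(length(curies), 5L)
    for (cu in curies) {
      expect_identical(sv_fetch(sv, cu), s)
    }
    # the bare-digest spelling resolves like the stored ga4gh record
    expect_identical(sv_fetch(sv, paste0("sha512t24u:", sha512t24u(s))), s)
  }
})

test_that("translate_identifier filters, orders and round-trips", {
  sv <- local_repo()
  sv_store(sv, "ACGTACGT", "refseq:TEST0")
  digest <- sha512t24u("ACGTACGT")
  expect_identical(sv_translate_identifier(sv, "refseq:TEST0", "ga4gh"),
                   paste0("ga4gh:SQ.", digest))
  # converse direction: digest CURIE back to the conventional identifier
  expect_true("refseq:TEST0" %in%
                sv_translate_identifier(sv, paste0("ga4gh:SQ.", digest)))
  # deterministic (namespace, alias) ordering
  all_curies <- sv_translate_identifier(sv, "refseq:TEST0")
  expect_identical(all_curies, sort(all_curies))
  # empty filter -> empty result; sha512t24u target emits bare spelling
  expect_length(sv_translate_identifier(sv, "refseq:TEST0", character()), 0L)
  expect_identical(sv_translate_identifier(sv, "refseq:TEST0", "sha512t24u"),
                   paste0("sha512t24u:", digest))
  # round trip through any alias lands on the same sequence
  for (cu in all_curies) {
    expect_identical(sv_translate_identifier(sv, cu), all_curies)
  }
})

test_that("contains, list_ids and stats stay consistent", {
  sv <- local_repo()
  expect_false(sv_contains(sv, "refseq:TEST0"))
  sv_store(sv, "ACGTACGT", "refseq:TEST0")
  sv_store(sv, "TTTTCCCC", "refseq:TEST1")
  sv_store(sv, "ACGTACGT", "other:X")
  expect_true(sv_contains(sv, "refseq:TEST0"))
  expect_true(sv_contains(sv, "TEST1"))
  expect_false(sv_contains(sv, "refseq:ABSENT"))
  ids <- sv_list_ids(sv)
  expect_identical(anyDuplicated(ids), 0L)
  expect_setequal(ids, c(sha512t24u("ACGTACGT"), sha512t24u("TTTTCCCC")))
  expect_identical(sv_stats(sv)$n_sequences, 2L)
})

test_that("map-style access matches fetch byte for byte", {
  sv <- local_repo()
  set.seed(32)
  s <- rand_seq(500)
  sv_store(sv, s, "custom:MAP0")
  sv_commit(sv)
  proxy <- sv[["custom:MAP0"]]
  expect_identical(length(proxy), 500L)
  expect_identical(as.character(proxy), s)
  expect_identical(proxy[], s)
  for (k in 1:25) {
    a <- sample(0:500, 1)
    b <- if (a == 500) 500 else sample(a:500, 1)
    expect_identical(proxy[a, b], sv_fetch(sv, "custom:MAP0", a, b))
  }
  expect_error(sv[["custom:ABSENT"]], class = "sv_not_found_error")
})

test_that("ambiguous bare aliases raise, namespaced lookups disambiguate", {
  sv <- local_repo()
  sv_store(sv, "ACGTACGT", "nsA:SHARED")
  sv_store(sv, "TTGGCCAA", "nsB:SHARED")
  expect_error(sv_fetch(sv, "SHARED"), class = "sv_ambiguity_error")
  expect_identical(sv_fetch(sv, "nsA:SHARED"), "ACGTACGT")
  expect_identical(sv_fetch(sv, "nsB:SHARED"), "TTGGCCAA")
})

test_that("snapshots hard-link volumes, copy databases and serve identically", {
  root <- local_repo_root()
  sv <- seqvault(root, writeable = TRUE)
  set.seed(33)
  seqs <- vapply(rep(200, 5), rand_seq, "")
  for (i in seq_along(seqs)) sv_store(sv, seqs[[i]], sprintf("custom:S%d", i))
  sv_commit(sv)

  dest <- tempfile("snap-")
  withr::defer(unlink(dest, recursive = TRUE))
  rep1 <- sv_snapshot(sv, dest)
  expect_identical(rep1$n_files_copied, 2L)
  expect_identical(rep1$n_files_linked, 3L)   # volume + .fai + .gzi

  vols <- fd_volumes(sv$fd)$relpath
  for (v in vols) {
    src <- file.path(root, "sequences", v)
    dst <- file.path(dest, "sequences", v)
    expect_equal(fs::file_info(src)$hard_links, 2)
    expect_identical(fs::file_info(src)$inode, fs::file_info(dst)$inode)
  }

  snap <- seqvault(dest)
  withr::defer(sv_close(snap))
  for (i in seq_along(seqs)) {
    expect_identical(sv_fetch(snap, sprintf("custom:S%d", i)), seqs[[i]])
  }
  expect_identical(sv_stats(snap), sv_stats(sv))
  # the snapshot is read-only
  expect_error(sv_store(snap, "ACGT"), class = "sv_readonly_error")

  # incrementality: after one more commit, a second snapshot creates only
  # the new volume (plus db copies); old volumes gain one more link
  sv_store(sv, rand_seq(300), "custom:NEW")
  sv_commit(sv)
  dest2 <- tempfile("snap-")
  withr::defer(unlink(dest2, recursive = TRUE))
  sv_snapshot(sv, dest2)
  new_vols <- setdiff(fd_volumes(sv$fd)$relpath, vols)
  expect_length(new_vols, 1L)
  for (v in vols) {
    expect_equal(fs::file_info(file.path(root, "sequences", v))$hard_links, 3)
  }
  expect_equal(
    fs::file_info(file.path(root, "sequences", new_vols))$hard_links, 2)
  # non-empty destination refused
  expect_error(sv_snapshot(sv, dest), class = "sv_usage_error")
  sv_close(sv)
})

test_that("slice fetch latency stays in the millisecond range", {
  sv <- local_repo()
  set.seed(34)
  s <- rand_seq(2e5)
  sv_store(sv, s, "custom:CHR")
  sv_commit(sv)
  times <- vapply(1:50, function(i) {
    a <- sample(0:(2e5 - 30), 1)
    system.time(sv_fetch(sv, "custom:CHR", a, a + 30))[["elapsed"]]
  }, 0)
  med_ms <- stats::median(times) * 1000
  testthat::expect_lt(med_ms, 10)
})
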