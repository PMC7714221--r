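# HTTP surfaces: native /v1 REST and the refget protocol, served by a
# background process and exercised over real sockets.

make_served_repo <- function(env = parent.frame()) {
  root <- local_repo_root(env = env)
  sv <- seqvault(root, writeable = TRUE)
  sv_store(sv, "ACGTACGTGGCCTTAA", "refseq:TEST0")
  sv_store(sv, "MGSKVLLTTE", "custom:PROT1")
  set.seed(55)
  long_seq <- rand_seq(5000)
  sv_store(sv, long_seq, "custom:LONG1")
  sv_commit(sv)
  sv_close(sv)
  srv <- start_test_server(root, env = env)
  srv$long_seq <- long_seq
  srv
}

test_that("the native surface serves ping, sequences, slices and metadata", {
  srv <- make_served_repo()
  h <- curl::new_handle()

  r <- http_get(paste0(srv$url, "/v1/ping"), h)
  expect_identical(r$status, 200L)
  ping <- jsonlite::fromJSON(r$body)
  expect_equal(ping$n_sequences, 3)

  r <- http_get(paste0(srv$url, "/v1/sequence/refseq:TEST0?start=2&end=4"), h)
  expect_identical(r$status, 200L)
  expect_identical(r$body, "GT")
  expect_match(r$type, "^text/plain")

  r <- http_get(paste0(srv$url, "/v1/sequence/refseq:TEST0"), h)
  expect_identical(r$body, "ACGTACGTGGCCTTAA")
  # bare globally-unique alias works over HTTP too
  r <- http_get(paste0(srv$url, "/v1/sequence/PROT1"), h)
  expect_identical(r$body, "MGSKVLLTTE")

  r <- http_get(paste0(srv$url, "/v1/metadata/refseq:TEST0"), h)
  expect_identical(r$status, 200L)
  md <- jsonlite::fromJSON(r$body)
  expect_equal(md$length, 16)
  expect_identical(md$alphabet, "ACGT")
  expect_length(md$aliases, 5L)
  expect_identical(md$aliases, sort(md$aliases))
})

test_that("the native surface maps failure modes onto 404/422/400", {
  srv <- make_served_repo()
  h <- curl::new_handle()
  expect_identical(
    http_get(paste0(srv$url, "/v1/sequence/refseq:ABSENT"), h)$status, 404L)
  expect_identical(
    http_get(paste0(srv$url, "/v1/metadata/refseq:ABSENT"), h)$status, 404L)
  expect_identical(
    http_get(paste0(srv$url, "/v1/sequence/refseq:TEST0?start=5&end=2"), h)$status,
    422L)
  expect_identical(
    http_get(paste0(srv$url, "/v1/sequence/refseq:TEST0?start=0&end=9999"), h)$status,
    422L)
  expect_identical(
    http_get(paste0(srv$url, "/v1/sequence/refseq:TEST0?start=x"), h)$status,
    400L)
  # write methods are rejected on the read-only interface
  hp <- curl::new_handle()
  curl::handle_setopt(hp, customrequest = "POST")
  r <- curl::curl_fetch_memory(paste0(srv$url, "/v1/sequence/refseq:TEST0"), hp)
  expect_identical(r$status_code, 405L)
})

test_that("the refget surface serves digests in all three spellings", {
  srv <- make_served_repo()
  h <- curl::new_handle()
  seq0 <- "ACGTACGTGGCCTTAA"
  t24u <- sha512t24u(seq0)
  md5hex <- paste(openssl::md5(charToRaw(seq0)))
  trunc512 <- paste(format(unclass(openssl::sha512(charToRaw(seq0)))[1:24]),
                    collapse = "")

  r <- http_get(paste0(srv$url, "/sequence/", t24u), h)
  expect_identical(r$status, 200L)
  expect_identical(r$body, seq0)
  expect_match(r$type, "vnd.ga4gh.refget", fixed = TRUE)

  expect_identical(http_get(paste0(srv$url, "/sequence/", md5hex), h)$body, seq0)
  expect_identical(http_get(paste0(srv$url, "/sequence/", trunc512), h)$body, seq0)

  r <- http_get(paste0(srv$url, "/sequence/", t24u, "?start=0&end=4"), h)
  expect_identical(r$body, "ACGT")

  md <- jsonlite::fromJSON(
    http_get(paste0(srv$url, "/sequence/", t24u, "/metadata"), h)$body)
  expect_identical(md$metadata$md5, md5hex)
  expect_identical(md$metadata$trunc512, trunc512)
  expect_identical(md$metadata$ga4gh, paste0("ga4gh:SQ.", t24u))
  expect_equal(md$metadata$length, 16)

  info <- jsonlite::fromJSON(
    http_get(paste0(srv$url, "/sequence/service-info"), h)$body)
  expect_false(info$service$circular_supported)

  # refget requires bare digests: namespaced identifiers are not found
  expect_identical(
    http_get(paste0(srv$url, "/sequence/refseq:TEST0"), h)$status, 404L)
  # out-of-bounds -> 416, start > end -> 501 (circular semantics)
  expect_identical(
    http_get(paste0(srv$url, "/sequence/", t24u, "?start=0&end=9999"), h)$status,
    416L)
  expect_identical(
    http_get(paste0(srv$url, "/sequence/", t24u, "?start=5&end=2"), h)$status,
    501L)
})

test_that("both HTTP surfaces agree with the native interface on slices", {
  srv <- make_served_repo()
  h <- curl::new_handle()
  root <- jsonlite::fromJSON(http_get(paste0(srv$url, "/v1/ping"), h)$body)$repository_root
  sv <- seqvault(root)
  withr::defer(sv_close(sv))
  t24u <- sha512t24u(srv$long_seq)
  set.seed(56)
  for (k in 1:100) {
    a <- sample(0:5000, 1)
    b <- if (a == 5000) 5000 else sample(a:5000, 1)
    native <- sv_fetch(sv, "custom:LONG1", a, b)
    expect_identical(substr(srv$long_seq, a + 1, b), native)
    rest <- http_get(sprintf("%s/v1/sequence/custom:LONG1?start=%d&end=%d",
                             srv$url, a, b), h)$body
    refget <- http_get(sprintf("%s/sequence/%s?start=%d&end=%d",
                               srv$url, t24u, a, b), h)$body
    expect_identical(rest, native)
    expect_identical(refget, native)
  }
})

test_that("service endpoints answer on an empty repository", {
  root <- local_repo_root()
  srv <- start_test_server(root)
  h <- curl::new_handle()
  r <- http_get(paste0(srv$url, "/v1/ping"), h)
  expect_identical(r$status, 200L)
  expect_equal(jsonlite::fromJSON(r$body)$n_sequences, 0)
  expect_identical(
    http_get(paste0(srv$url, "/sequence/service-info"), h)$status, 200L)
})
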