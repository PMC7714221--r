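# Shared test infrastructure: throwaway repositories, seeded random
# sequences, independent digest oracles (the `digest` package -- a separate
# SHA/MD5 implementation from the openssl one the package uses), and a
# background HTTP server for the service tests.

local_repo_root <- function(env = parent.frame()) {
  root <- tempfile("svrepo-")
  seqvault_init(root)
  withr::defer(unlink(root, recursive = TRUE), envir = env)
  root
}

local_repo <- function(writeable = TRUE, env = parent.frame()) {
  root <- local_repo_root(env = env)
  sv <- seqvault(root, writeable = writeable)
  withr::defer(sv_close(sv), envir = env)
  sv
}

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# independent oracles ------------------------------------------------------

oracle_sha512_raw <- function(x) {
  digest::digest(if (is.raw(x)) x else charToRaw(x),
                 algo = "sha512", serialize = FALSE, raw = TRUE)
}

oracle_md5_hex <- function(x) {
  digest::digest(if (is.raw(x)) x else charToRaw(x),
                 algo = "md5", serialize = FALSE)
}

oracle_sha1_hex <- function(x) {
  digest::digest(if (is.raw(x)) x else charToRaw(x),
                 algo = "sha1", serialize = FALSE)
}

# base64url re-encoder independent of the package internals
oracle_b64url <- function(raw) {
  b64 <- c(LETTERS, letters, 0:9, "-", "_")
  bits <- as.integer(rawToBits(raw))      # little-endian per byte
  bytes <- matrix(bits, nrow = 8)
  msb <- bytes[8:1, , drop = FALSE]       # big-endian bit rows
  stream <- as.vector(msb)
  n6 <- ceiling(length(stream) / 6)
  stream <- c(stream, rep(0L, n6 * 6 - length(stream)))
  idx <- colSums(matrix(stream, nrow = 6) * 2^(5:0)) + 1
  paste(b64[idx], collapse = "")
}

# decode an unpadded base64url string to raw bytes
base64url_decode_test <- function(x) {
  pad <- (4L - nchar(x) %% 4L) %% 4L
  openssl::base64_decode(paste0(chartr("-_", "+/", x), strrep("=", pad)))
}

# resolve an identifier to its internal digest key via the public API
sv_resolve_test <- function(sv, identifier) {
  sub("^sha512t24u:", "",
      sv_translate_identifier(sv, identifier, "sha512t24u"))
}

# HTTP ---------------------------------------------------------------------

http_get <- function(url, handle = curl::new_handle()) {
  r <- curl::curl_fetch_memory(url, handle = handle)
  list(status = r$status_code, body = rawToChar(r$content),
       type = r$type)
}

start_test_server <- function(root, env = parent.frame()) {
  port <- httpuv::randomPort()
  px <- callr::r_bg(
    function(root, port) seqvault::seqvault_serve(root, port = port),
    args = list(root = root, port = port))
  withr::defer(px$kill(), envir = env)
  url <- sprintf("http://127.0.0.1:%d", port)
  for (i in 1:150) {
    ok <- tryCatch(http_get(paste0(url, "/v1/ping"))$status == 200,
                   error = function(e) FALSE)
    if (ok) return(list(process = px, url = url, port = port))
    if (!px$is_alive()) {
      stop("test server died:\n",
           paste(px$read_all_error_lines(), collapse = "\n"))
    }
    Sys.sleep(0.1)
  }
  stop("test server did not come up")
}
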