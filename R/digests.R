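#' Truncated SHA-512 digest with URL-safe base64 encoding (sha512t24u)
#'
#' Computes the SHA-512 digest of a byte string, truncates it to its first
#' 24 bytes (192 bits), and encodes those bytes with unpadded URL-safe
#' base64. The result is always 32 characters over the alphabet
#' `A-Z a-z 0-9 - _`, making it usable directly in URLs and file names.
#' The truncation keeps the standard SHA-512 initialization vector (it is a
#' plain prefix of the full digest, not a SHA-512/t variant), so longer
#' truncations of the same input share this digest as a prefix.
#'
#' @param blob A raw vector, or a length-1 character string which is
#'   encoded as UTF-8 bytes before hashing.
#' @return A 32-character digest string.
#' @examples
#' sha512t24u("ACGT")
#' sha512t24u(charToRaw("ACGT"))
#' @export
sha512t24u <- function(blob) {
  if (is.character(blob)) {
    if (length(blob) != 1L || is.na(blob)) {
      sv_usage("`blob` must be a raw vector or a single character string")
    }
    blob <- charToRaw(enc2utf8(blob))
  }
  if (!is.raw(blob)) {
    sv_usage("`blob` must be a raw vector or a single character string")
  }
  base64url_encode(unclass(openssl::sha512(blob))[seq_len(24L)])
}

# unpadded URL-safe base64 of a raw vector
base64url_encode <- function(raw) {
  gsub("=+$", "", chartr("+/", "-_", openssl::base64_encode(raw)))
}

# inverse; accepts unpadded input
base64url_decode <- function(x) {
  pad <- (4L - nchar(x) %% 4L) %% 4L
  openssl::base64_decode(paste0(chartr("-_", "+/", x), strrep("=", pad)))
}

#' SEGUID checksum of a sequence
#'
#' The SEquence Globally Unique IDentifier: standard (not URL-safe) base64
#' encoding of the SHA-1 digest of the uppercased sequence, with trailing
#' `=` padding removed; always 27 characters. Note the result may contain
#' `+` or `/`, which is why it is unsuited to URLs.
#'
#' @param seq Non-empty sequence string (ASCII).
#' @return A 27-character SEGUID string.
#' @examples
#' seguid("ACGT")
#' @export
seguid <- function(seq) {
  seq <- check_sequence_ascii(seq)
  b <- charToRaw(toupper(seq))
  gsub("=+$", "", openssl::base64_encode(unclass(openssl::sha1(b))))
}

#' Computed identifiers for a sequence
#'
#' Returns the four digest-based identifiers stored for every sequence:
#' hex MD5, SEGUID, hex SHA-1, and the GA4GH form `SQ.<sha512t24u>`.
#' The sequence is uppercased before hashing, the single normalization
#' point of the package: `"acgt"` and `"ACGT"` yield identical identifiers
#' and deduplicate to one stored record.
#'
#' @param seq Non-empty sequence string (ASCII).
#' @return A data.frame with columns `namespace` and `alias`, four rows,
#'   in a fixed order (MD5, SEGUID, SHA1, ga4gh).
#' @examples
#' compute_identifiers("ACGT")
#' @export
compute_identifiers <- function(seq) {
  seq <- toupper(check_sequence_ascii(seq))
  b <- charToRaw(seq)
  data.frame(
    namespace = c("MD5", "SEGUID", "SHA1", "ga4gh"),
    alias = c(
      as.character(openssl::md5(b)),
      seguid(seq),
      as.character(openssl::sha1(b)),
      paste0("SQ.", sha512t24u(b))
    ),
    stringsAsFactors = FALSE
  )
}

#' Birthday-bound collision probability for truncated digests
#'
#' Probability that at least two of `n_messages` uniformly random digests of
#' `digest_bits` bits collide. For small message counts the exact birthday
#' product \eqn{1 - \prod_{k=1}^{n-1} (1 - k/2^b)} is evaluated in log
#' space; for large counts the classical approximation
#' \eqn{1 - \exp(-n(n-1)/2^{b+1})} is used, also in log space, so the
#' function stays finite and accurate for inputs as extreme as
#' \eqn{n = 10^{18}, b = 192}. Monotone increasing in `n_messages` and
#' decreasing in `digest_bits`.
#'
#' @param n_messages Number of messages, >= 1.
#' @param digest_bits Digest width in bits, >= 1.
#' @return Collision probability in `[0, 1]`.
#' @examples
#' collision_probability(1e18, 192)  # < 1e-21
#' collision_probability(2, 1)       # exactly 0.5
#' @export
collision_probability <- function(n_messages, digest_bits) {
  n <- as.numeric(n_messages)
  b <- as.numeric(digest_bits)
  if (length(n) != 1L || length(b) != 1L || is.na(n) || is.na(b) ||
      n < 1 || b < 1) {
    sv_usage("n_messages and digest_bits must be single numbers >= 1")
  }
  if (n < 2) {
    return(0)
  }
  if (n <= 1e6) {
    k <- seq_len(n - 1)
    frac <- k * 2^-b
    if (any(frac >= 1)) {
      return(1)
    }
    -expm1(sum(log1p(-frac)))
  } else {
    log_lambda <- log(n) + log(n - 1) - (b + 1) * log(2)
    -expm1(-exp(log_lambda))
  }
}

# --- shared sequence validation ------------------------------------------

# non-empty, single, ASCII character string; returns seq unchanged
check_sequence_ascii <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    sv_usage("sequence must be a single character string")
  }
  if (nchar(seq) == 0L) {
    sv_usage("empty sequences are not storable or hashable")
  }
  if (any(charToRaw(seq) > as.raw(0x7f))) {
    sv_usage("sequence contains non-ASCII characters")
  }
  seq
}

# residue alphabet accepted by the sequence store: letters plus the
# gap/stop/translation symbols used in IUPAC-style FASTA records
check_sequence_residues <- function(seq) {
  seq <- check_sequence_ascii(seq)
  if (grepl("[^A-Za-z*.+-]", seq)) {
    sv_usage("sequence contains non-residue characters (allowed: A-Z a-z * . + -)")
  }
  seq
}

# single normalization point used before hashing and storage
normalize_sequence <- function(seq) {
  toupper(check_sequence_residues(seq))
}
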