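# CURIE handling and namespace canonicalization.
#
# Identifiers are W3C Compact URIs, "prefix:reference", where the prefix is
# the namespace and the reference the alias. The reference may contain
# colons; the prefix ends at the first colon. A string without a colon is a
# bare alias (namespace unknown) and is resolved across all namespaces.

# canonical lowercase identifiers.org-style prefixes for common authorities;
# digest namespaces keep their conventional spellings
.ns_aliases <- c(
  "RefSeq"     = "refseq",
  "NCBI"       = "refseq",
  "Ensembl"    = "ensembl",
  "ENSEMBL"    = "ensembl",
  "LRG"        = "lrg",
  "GRCh"       = "grch",
  "md5"        = "MD5",
  "Md5"        = "MD5",
  "seguid"     = "SEGUID",
  "Seguid"     = "SEGUID",
  "sha1"       = "SHA1",
  "Sha1"       = "SHA1",
  "GA4GH"      = "ga4gh"
)

# namespaces whose alias value is a pure function of the sequence; these
# associations are never deprecated
.computed_namespaces <- c("MD5", "SEGUID", "SHA1", "ga4gh")

normalize_namespace <- function(ns) {
  if (!is.character(ns) || length(ns) != 1L || is.na(ns) || !nzchar(ns)) {
    sv_parse_error("namespace must be a non-empty string")
  }
  if (ns %in% names(.ns_aliases)) .ns_aliases[[ns]] else ns
}

#' Parse an identifier into namespace and alias
#'
#' Splits `"prefix:reference"` at the first colon. Input without a colon is
#' treated as a bare alias (`namespace` is `NA`), to be resolved across all
#' namespaces when globally unique. Known namespace spellings are
#' canonicalized (`RefSeq` -> `refseq`, `md5` -> `MD5`, ...).
#'
#' @param x Identifier string.
#' @return List with elements `namespace` (string or `NA`) and `alias`.
#' @examples
#' parse_identifier("refseq:NM_000551.3")
#' parse_identifier("NM_000551.3")
#' @export
parse_identifier <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    sv_parse_error("identifier must be a non-empty string")
  }
  pos <- regexpr(":", x, fixed = TRUE)
  if (pos < 0L) {
    return(list(namespace = NA_character_, alias = x))
  }
  if (pos == 1L) {
    sv_parse_error(sprintf("malformed CURIE (empty prefix): '%s'", x))
  }
  prefix <- substr(x, 1L, pos - 1L)
  reference <- substr(x, pos + 1L, nchar(x))
  if (!nzchar(reference)) {
    sv_parse_error(sprintf("malformed CURIE (empty reference): '%s'", x))
  }
  list(namespace = normalize_namespace(prefix), alias = reference)
}

# strict variant: a namespace is required (used by sv_store identifiers)
parse_curie <- function(x) {
  p <- parse_identifier(x)
  if (is.na(p$namespace)) {
    sv_parse_error(sprintf("expected a namespaced CURIE 'prefix:reference', got '%s'", x))
  }
  p
}

format_curie <- function(namespace, alias) paste0(namespace, ":", alias)

# map query-time digest spellings onto the stored record: the bare
# sha512t24u namespace resolves against the stored ga4gh "SQ.<digest>" row
canonical_query <- function(namespace, alias) {
  if (identical(namespace, "sha512t24u")) {
    return(list(namespace = "ga4gh", alias = paste0("SQ.", alias)))
  }
  list(namespace = namespace, alias = alias)
}
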