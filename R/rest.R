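# Read-only HTTP access to a repository: the native surface under /v1 and a
# refget-compatible surface under /sequence. Both are GET-only and are
# backed by the same open repo instance.
#
# Error mapping, native surface: 404 unknown identifier, 422 bad range or
# ambiguous bare alias (candidates listed in the body), 400 malformed
# parameters. refget surface: 404 unknown digest, 416 out-of-bounds range,
# 501 start > end (circular semantics, unsupported), 400 malformed
# parameters. Any non-GET method: 405.

http_response <- function(status, body, type = "application/json") {
  list(status = status, headers = list("Content-Type" = type), body = body)
}

json_response <- function(status, x) {
  http_response(status, jsonlite::toJSON(x, auto_unbox = TRUE, null = "null"))
}

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) == 2L) out[[httpuv::decodeURIComponent(p[[1]])]] <- httpuv::decodeURIComponent(p[[2]])
  }
  out
}

# query bound -> integer or NULL; signals sv_parse_error on malformed input
query_bound <- function(q, name) {
  v <- q[[name]]
  if (is.null(v)) return(NULL)
  if (!grepl("^[0-9]+$", v)) {
    sv_parse_error(sprintf("query parameter '%s' must be a non-negative integer", name))
  }
  as.numeric(v)
}

refget_media_type <- "text/vnd.ga4gh.refget+plain; charset=us-ascii"

# resolve a bare refget digest (no namespace allowed): hex MD5 (32), hex
# trunc512 (48, converted to the base64url spelling), or base64url
# sha512t24u (32)
refget_resolve <- function(sv, digest) {
  if (grepl(":", digest, fixed = TRUE)) {
    sv_not_found("refget queries require bare digests, not namespaced identifiers")
  }
  ids <- character()
  if (grepl("^[0-9a-fA-F]{32}$", digest)) {
    ids <- sa_translate(sv$sa, tolower(digest), namespace = "MD5")
  } else if (grepl("^[0-9a-fA-F]{48}$", digest)) {
    t24u <- base64url_encode(as.raw(strtoi(
      substring(digest, seq(1, 47, 2), seq(2, 48, 2)), 16L)))
    ids <- sa_translate(sv$sa, t24u, namespace = "sha512t24u")
  } else if (grepl("^[A-Za-z0-9_-]{32}$", digest)) {
    ids <- sa_translate(sv$sa, digest, namespace = "sha512t24u")
  }
  if (length(ids) == 0L) {
    sv_not_found(sprintf("unknown digest: %s", digest))
  }
  ids[[1L]]
}

#' HTTP application serving a repository
#'
#' Builds the httpuv application implementing the native REST interface
#' (`/v1/ping`, `/v1/sequence/{identifier}`, `/v1/metadata/{identifier}`)
#' and the refget protocol interface (`/sequence/service-info`,
#' `/sequence/{digest}`, `/sequence/{digest}/metadata`). Both surfaces are
#' read-only (GET only) and use 0-based half-open `start`/`end` query
#' parameters. The refget surface requires bare digests and serves both
#' the base64url (`sha512t24u`/ga4gh) and hex (`trunc512`, MD5)
#' spellings.
#'
#' @param sv An open [seqvault()] (typically read-only).
#' @param service_name Reported service name.
#' @return A list with a `call` element, suitable for
#'   [httpuv::startServer()].
#' @export
seqvault_app <- function(sv, service_name = "seqvault") {
  version <- as.character(utils::packageVersion("seqvault"))

  handle_native_sequence <- function(identifier, q) {
    body <- sv_fetch(sv, identifier,
                     start = query_bound(q, "start"), end = query_bound(q, "end"))
    http_response(200L, body, type = "text/plain; charset=us-ascii")
  }

  handle_native_metadata <- function(identifier) {
    json_response(200L, sv_metadata(sv, identifier))
  }

  handle_ping <- function() {
    st <- sv_stats(sv)
    json_response(200L, list(
      service_name = service_name,
      version = version,
      repository_root = sv$root,
      n_sequences = st$n_sequences))
  }

  handle_refget_service_info <- function() {
    json_response(200L, list(service = list(
      supported_api_versions = list("1.0"),
      circular_supported = FALSE,
      subsequence_limit = NULL,
      algorithms = list("md5", "ga4gh", "trunc512"))))
  }

  handle_refget_sequence <- function(digest, q) {
    seq_id <- refget_resolve(sv, digest)
    len <- fd_info(sv$fd, seq_id)$len
    start <- query_bound(q, "start")
    end <- query_bound(q, "end")
    if (!is.null(start) && !is.null(end) && start > end) {
      sv_abort("start greater than end implies circular semantics, which are unsupported",
               "sv_circular_error")
    }
    if ((!is.null(start) && start > len) || (!is.null(end) && end > len)) {
      sv_range_error("requested range is beyond the sequence bounds")
    }
    body <- fd_fetch(sv$fd, seq_id, start = start, end = end)
    http_response(200L, body, type = refget_media_type)
  }

  handle_refget_metadata <- function(digest) {
    seq_id <- refget_resolve(sv, digest)
    info <- fd_info(sv$fd, seq_id)
    aliases <- sa_find_aliases(sv$sa, seq_id = seq_id, current_only = TRUE)
    md5 <- aliases$alias[aliases$namespace == "MD5"][1]
    ga <- aliases$alias[aliases$namespace == "ga4gh"][1]
    t24u <- sub("^SQ\\.", "", ga)
    trunc512 <- paste(format(base64url_decode(t24u)), collapse = "")
    json_response(200L, list(metadata = list(
      md5 = md5,
      ga4gh = paste0("ga4gh:", ga),
      trunc512 = trunc512,
      length = info$len,
      aliases = lapply(seq_len(nrow(aliases)), function(i) {
        list(naming_authority = aliases$namespace[[i]], alias = aliases$alias[[i]])
      }))))
  }

  route <- function(req) {
    if (!identical(req$REQUEST_METHOD, "GET")) {
      return(http_response(405L, "read-only interface: only GET is accepted",
                           type = "text/plain"))
    }
    path <- req$PATH_INFO
    q <- parse_query_string(req$QUERY_STRING)
    if (path == "/v1/ping") return(handle_ping())
    m <- regmatches(path, regexec("^/v1/sequence/(.+)$", path))[[1]]
    if (length(m)) {
      return(handle_native_sequence(httpuv::decodeURIComponent(m[[2]]), q))
    }
    m <- regmatches(path, regexec("^/v1/metadata/(.+)$", path))[[1]]
    if (length(m)) {
      return(handle_native_metadata(httpuv::decodeURIComponent(m[[2]])))
    }
    if (path == "/sequence/service-info") return(handle_refget_service_info())
    m <- regmatches(path, regexec("^/sequence/([^/]+)/metadata$", path))[[1]]
    if (length(m)) {
      return(handle_refget_metadata(httpuv::decodeURIComponent(m[[2]])))
    }
    m <- regmatches(path, regexec("^/sequence/([^/]+)$", path))[[1]]
    if (length(m)) {
      return(handle_refget_sequence(httpuv::decodeURIComponent(m[[2]]), q))
    }
    http_response(404L, "no such route", type = "text/plain")
  }

  refget_path <- function(req) {
    startsWith(req$PATH_INFO, "/sequence/")
  }

  list(call = function(req) {
    tryCatch(
      route(req),
      sv_not_found_error = function(e) {
        http_response(404L, conditionMessage(e), type = "text/plain")
      },
      sv_range_error = function(e) {
        http_response(if (refget_path(req)) 416L else 422L,
                      conditionMessage(e), type = "text/plain")
      },
      sv_circular_error = function(e) {
        http_response(501L, conditionMessage(e), type = "text/plain")
      },
      sv_ambiguity_error = function(e) {
        http_response(422L, paste0(
          conditionMessage(e), "\ncandidates: ",
          paste(e$candidates, collapse = ", ")), type = "text/plain")
      },
      sv_parse_error = function(e) {
        http_response(400L, conditionMessage(e), type = "text/plain")
      },
      seqvault_error = function(e) {
        http_response(400L, conditionMessage(e), type = "text/plain")
      },
      error = function(e) {
        http_response(500L, conditionMessage(e), type = "text/plain")
      })
  })
}

#' Serve a repository over HTTP
#'
#' Opens `root` read-only and blocks, serving the application built by
#' [seqvault_app()]. Intended to be run from the command line
#' (`seqvault serve`) or a background process.
#'
#' @param root Repository root.
#' @param host Interface to bind (default loopback).
#' @param port TCP port.
#' @param service_name Reported service name.
#' @export
seqvault_serve <- function(root, host = "127.0.0.1", port = 8037,
                           service_name = "seqvault") {
  sv <- seqvault(root, writeable = FALSE)
  on.exit(sv_close(sv), add = TRUE)
  app <- seqvault_app(sv, service_name = service_name)
  httpuv::runServer(host, port, app)
}
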