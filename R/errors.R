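# Condition constructors. Every error raised by the package carries the
# "seqvault_error" class plus one of the specific classes below, so callers
# (and the HTTP layer) can dispatch on failure mode rather than message text.

sv_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "seqvault_error", "error")))
}

sv_not_found <- function(message, ...) sv_abort(message, "sv_not_found_error", ...)

sv_range_error <- function(message, ...) sv_abort(message, "sv_range_error", ...)

sv_readonly <- function(message = "repository instance is read-only", ...) {
  sv_abort(message, "sv_readonly_error", ...)
}

# candidates: character vector of "namespace:alias" forms that matched
sv_ambiguous <- function(message, candidates = character(), ...) {
  sv_abort(message, "sv_ambiguity_error", candidates = candidates, ...)
}

sv_referential <- function(message, ...) sv_abort(message, "sv_referential_error", ...)

sv_usage <- function(message, ...) sv_abort(message, "sv_usage_error", ...)

sv_parse_error <- function(message, ...) sv_abort(message, "sv_parse_error", ...)

sv_io_error <- function(message, ...) sv_abort(message, "sv_io_error", ...)
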