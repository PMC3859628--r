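# Classed conditions used throughout the package. Every error raised by
# adrsub carries class "adrsub_error" plus one subclass naming the failure
# family, so callers (and the execution engine) can react by class rather
# than by message matching.

adr_abort <- function(message, class, ..., call = sys.call(-1)) {
  stop(errorCondition(message, ..., class = c(class, "adrsub_error"),
                      call = call))
}

abort_validation <- function(message, ...) {
  adr_abort(message, "adrsub_validation_error", ...)
}

abort_config <- function(message, ...) {
  adr_abort(message, "adrsub_config_error", ...)
}

abort_state <- function(message, ...) {
  adr_abort(message, "adrsub_state_error", ...)
}

abort_not_found <- function(message, ...) {
  adr_abort(message, "adrsub_not_found_error", ...)
}

abort_parse <- function(message, ...) {
  adr_abort(message, "adrsub_parse_error", ...)
}

abort_mapping <- function(message, ...) {
  adr_abort(message, "adrsub_mapping_error", ...)
}

abort_degenerate <- function(message, ...) {
  adr_abort(message, "adrsub_degenerate_table_error", ...)
}

abort_conflict <- function(message, ...) {
  adr_abort(message, "adrsub_conflict_error", ...)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}
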