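# Central status-code registry for the monitoring section of the
# interchange dialect. Only code 41 (internal database-connection failure)
# is fixed by the platform convention the dialect follows; the remaining
# codes are artifact-defined, grouped by decade: 1x input validation,
# 2x communication, 4x internal provider errors.

.status_registry <- new.env(parent = emptyenv())

.default_status_codes <- list(
  list(code = 0L,  message = "success"),
  list(code = 10L, message = "invalid input document"),
  list(code = 11L, message = "empty dataset"),
  list(code = 12L, message = "vocabulary mapping miss for one or more pairs"),
  list(code = 20L, message = "communication failure with knowledge source"),
  list(code = 40L, message = "internal provider error"),
  list(code = 41L, message = "internal service problem: database connection failure")
)

reset_status_registry <- function() {
  rm(list = ls(.status_registry), envir = .status_registry)
  for (sc in .default_status_codes) {
    assign(as.character(sc$code), sc$message, envir = .status_registry)
  }
}

#' Register a monitoring status code
#'
#' The registry is closed: [status_code()] refuses to construct a code that
#' has not been registered. Code 0 always means success; 41 always means an
#' internal database-connection failure.
#'
#' @param code Integer code.
#' @param message Default human-readable message.
#' @return The code, invisibly.
#' @export
register_status_code <- function(code, message) {
  if (!is_count(code)) abort_validation("status code must be a non-negative integer")
  if (!is_string(message)) abort_validation("status message must be a string")
  assign(as.character(as.integer(code)), message, envir = .status_registry)
  invisible(as.integer(code))
}

#' Construct a registered status code
#'
#' @param code Integer code previously registered (see [status_codes()]).
#' @param message Optional message overriding the registered default.
#' @return An object of class `status_code` with fields `code`, `message`.
#' @examples
#' status_code(0)
#' status_code(41)
#' @export
status_code <- function(code, message = NULL) {
  if (!is_count(code)) abort_validation("status code must be a non-negative integer")
  key <- as.character(as.integer(code))
  if (!exists(key, envir = .status_registry, inherits = FALSE)) {
    abort_validation(sprintf("status code %s is not registered", key))
  }
  if (is.null(message)) message <- get(key, envir = .status_registry)
  structure(list(code = as.integer(code), message = message),
            class = "status_code")
}

#' List registered status codes
#'
#' @return Data frame with columns `code`, `message`, ordered by code.
#' @export
status_codes <- function() {
  codes <- as.integer(ls(.status_registry))
  codes <- sort(codes)
  data.frame(code = codes,
             message = vapply(as.character(codes), get,
                              character(1), envir = .status_registry),
             row.names = NULL)
}

#' @export
print.status_code <- function(x, ...) {
  cat(sprintf("<status %d: %s>\n", x$code, x$message))
  invisible(x)
}

reset_status_registry()
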