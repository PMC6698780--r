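# Classed conditions used across the package. Every error raised by
# screencomposer carries class "sc_error" plus a specific subclass so that
# callers (and tests) can distinguish failure modes without string matching.

sc_abort <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(subclass, "sc_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

abort_invalid <- function(message, ...) {
  sc_abort("sc_invalid_argument", message, call = sys.call(-1), ...)
}

abort_state <- function(message, ...) {
  sc_abort("sc_state_error", message, call = sys.call(-1), ...)
}

abort_compose <- function(message, path, ...) {
  sc_abort("sc_composition_error",
           sprintf("%s (at node %s)", message, path),
           call = sys.call(-1), path = path, ...)
}

abort_color <- function(message, ...) {
  sc_abort("sc_color_parse_error", message, call = sys.call(-1), ...)
}

abort_io <- function(message, ...) {
  sc_abort("sc_io_error", message, call = sys.call(-1), ...)
}

#' Signal that the user aborted the session
#'
#' Raised when a quit event reaches the event listener (for example when the
#' subject closes the window). Harness code catches this condition class to
#' flush partial results before exiting.
#'
#' @param message Condition message.
#' @return Does not return; signals a condition of class `"sc_user_abort"`.
#' @export
user_abort <- function(message = "session aborted by user") {
  sc_abort("sc_user_abort", message, call = sys.call(-1))
}
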