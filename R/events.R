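# Poll-based input abstraction. The listener never talks to hardware
# directly: it polls an EventSource contract (poll() returns the pending
# events, non-blocking, each event delivered at most once, in arrival order)
# and tells time through a Clock contract (now()/sleep()). Tests and replays
# inject a simulated clock and a scripted source, so every timing contract is
# checkable without a window and without real waiting.

#' Input event constructors
#'
#' Create typed device events. Each event carries exactly the fields of its
#' kind plus `time`, the event timestamp in seconds on the session clock.
#'
#' @param key Abstract key identifier (a string, e.g. `"F"`, `"return"`).
#' @param char A single unicode character.
#' @param x,y Pixel position of a mouse event.
#' @param button Mouse button id (1 = left).
#' @param time Timestamp in seconds.
#' @return An object of class `"sc_event"`.
#' @name input_events
NULL

new_event <- function(kind, time, ...) {
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time))
    abort_invalid("event time must be a single finite number")
  structure(list(kind = kind, time = as.numeric(time), ...),
            class = "sc_event")
}

#' @rdname input_events
#' @export
key_down_event <- function(key, time = 0) {
  if (!is.character(key) || length(key) != 1L)
    abort_invalid("key must be a single string")
  new_event("key_down", time, key = key)
}

#' @rdname input_events
#' @export
unicode_char_event <- function(char, time = 0) {
  if (!is.character(char) || length(char) != 1L || nchar(char) != 1L)
    abort_invalid("char must be a single character")
  new_event("unicode_char", time, char = char)
}

#' @rdname input_events
#' @export
mouse_event <- function(kind = c("mouse_down", "mouse_up", "mouse_move"),
                        x, y, button = 1L, time = 0) {
  kind <- match.arg(kind)
  new_event(kind, time, pos = c(as.integer(x), as.integer(y)),
            button = as.integer(button))
}

#' @rdname input_events
#' @export
quit_event <- function(time = 0) new_event("quit", time)

#' @export
format.sc_event <- function(x, ...) {
  sprintf("<event %s t=%.3f>", x$kind, x$time)
}

#' @export
print.sc_event <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Simulated clock
#'
#' A monotonic clock whose time only advances when `sleep()` (or `advance()`)
#' is called — simulated waiting costs no real time, so timeout contracts are
#' exact and fast to test.
#'
#' @param start Initial time in seconds.
#' @return A clock: a list with functions `now()`, `sleep(dt)`, and
#'   `advance(dt)`.
#' @export
simulated_clock <- function(start = 0) {
  t <- start
  adv <- function(dt) {
    if (dt < 0) abort_invalid("cannot sleep a negative duration")
    t <<- t + dt
    invisible(NULL)
  }
  structure(list(now = function() t, sleep = adv, advance = adv),
            class = "sc_clock")
}

#' Real (wall) clock
#'
#' Monotonic clock backed by the process's elapsed timer; `sleep()` calls
#' [Sys.sleep()]. Used for live sessions; tests use [simulated_clock()].
#'
#' @return A clock (see [simulated_clock()] for the contract).
#' @export
real_clock <- function() {
  t0 <- proc.time()[["elapsed"]]
  structure(list(
    now = function() proc.time()[["elapsed"]] - t0,
    sleep = function(dt) { if (dt > 0) Sys.sleep(dt); invisible(NULL) },
    advance = function(dt) { if (dt > 0) Sys.sleep(dt); invisible(NULL) }
  ), class = "sc_clock")
}

#' Scripted event source
#'
#' An event source that releases a predefined, timestamped list of events:
#' `poll()` returns (once, in order) every event whose `time` is at or before
#' the clock's current time. This is the replay/testing implementation of the
#' source contract.
#'
#' @param events List of events (see [input_events]) sorted by time; unsorted
#'   input is sorted stably by time.
#' @param clock The clock the timestamps refer to.
#' @return An event source: a list with `poll()`.
#' @export
scripted_event_source <- function(events, clock) {
  if (!all(vapply(events, inherits, TRUE, "sc_event")))
    abort_invalid("events must be a list of input events")
  times <- vapply(events, `[[`, 0, "time")
  events <- events[order(times)]
  delivered <- 0L
  structure(list(poll = function() {
    # release guard of 1 ns: accumulated float sleeps may land an ulp below
    # a timestamp that lies exactly on a poll tick
    now <- clock$now() + 1e-9
    out <- list()
    while (delivered < length(events) &&
           events[[delivered + 1L]]$time <= now) {
      delivered <<- delivered + 1L
      out[[length(out) + 1L]] <- events[[delivered]]
    }
    out
  }), class = "sc_event_source")
}

#' Read a scripted event stream from JSON lines
#'
#' Each line is an object `{"t": seconds, "kind": "...", ...}` with
#' kind-specific fields: `key` for `key_down`, `char` for `unicode_char`,
#' `x`/`y`/`button` for mouse kinds; `quit` needs only `t`.
#'
#' @param path Path to a JSON-lines file.
#' @return A list of events suitable for [scripted_event_source()].
#' @export
read_event_script <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such event script: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    t <- obj$t %||% 0
    switch(obj$kind,
      key_down = key_down_event(obj$key, t),
      unicode_char = unicode_char_event(obj$char, t),
      mouse_down = ,
      mouse_up = ,
      mouse_move = mouse_event(obj$kind, obj$x, obj$y, obj$button %||% 1L, t),
      quit = quit_event(t),
      abort_invalid(sprintf("unknown event kind '%s' in %s", obj$kind, path)))
  })
}

#' Timeout sentinel
#'
#' The distinguished "no event" value returned by the waiting primitives when
#' their timeout elapses. It is never a valid key or character; test with
#' [is_timeout()].
#'
#' @return The sentinel object.
#' @export
timeout_sentinel <- function() {
  structure(list(), class = "sc_timeout")
}

#' @rdname timeout_sentinel
#' @param x Any value.
#' @export
is_timeout <- function(x) inherits(x, "sc_timeout")

#' Create an event listener
#'
#' The listener couples an event source with a clock and an optional list of
#' permanent handlers. Permanent handlers see every polled event (before any
#' call-site handlers) on every wait, which is how cross-cutting reactions —
#' logging, a global abort key — are installed once for a whole session.
#'
#' @param source An event source (e.g. [scripted_event_source()]).
#' @param clock A clock (e.g. [simulated_clock()]).
#' @param handlers Optional list of permanent handler functions; a handler
#'   takes an event and returns `NULL` ("not consumed; keep listening") or
#'   any non-`NULL` result, which ends the wait.
#' @param poll_interval Clock seconds slept between empty polls (default
#'   0.001).
#' @return An object of class `"sc_event_listener"`.
#' @export
event_listener <- function(source, clock, handlers = list(),
                           poll_interval = 0.001) {
  if (!is.list(handlers) || !all(vapply(handlers, is.function, TRUE)))
    abort_invalid("handlers must be a list of functions")
  check_scalar_number(poll_interval, "poll_interval", strict_min = 0)
  structure(list(source = source, clock = clock, handlers = handlers,
                 poll_interval = poll_interval),
            class = "sc_event_listener")
}

# Offer one event to permanent then call-site handlers; first non-NULL result
# wins. A quit event is shown to permanent handlers first, then raises
# a user abort.
offer_event <- function(listener, handlers, ev) {
  for (h in listener$handlers) {
    r <- h(ev)
    if (!is.null(r)) return(r)
  }
  if (identical(ev$kind, "quit")) user_abort()
  for (h in handlers) {
    r <- h(ev)
    if (!is.null(r)) return(r)
  }
  NULL
}

#' Wait for the first event a handler consumes
#'
#' Repeatedly polls the event source. Every polled event is offered to the
#' listener's permanent handlers and then to the call-site `handlers`, in
#' order; the first non-`NULL` handler result is returned immediately. Events
#' arriving in the same poll batch are processed in batch order before the
#' timeout is checked. With no result by `timeout` seconds of clock time the
#' timeout sentinel is returned. Between empty polls the clock sleeps one
#' poll interval. A quit event raises a user-abort condition (after the
#' permanent handlers have seen it).
#'
#' @param listener An [event_listener()].
#' @param handlers List of handler functions for this call.
#' @param timeout Seconds to wait; `NULL` or a value `<= 0` waits
#'   indefinitely.
#' @return The first handler result, or the timeout sentinel.
#' @export
listen <- function(listener, handlers = list(), timeout = NULL) {
  if (!inherits(listener, "sc_event_listener"))
    abort_invalid("listener must be an event listener")
  if (!is.list(handlers) || !all(vapply(handlers, is.function, TRUE)))
    abort_invalid("handlers must be a list of functions")
  if (length(handlers) == 0L && length(listener$handlers) == 0L)
    abort_invalid("at least one handler is required (permanent handlers count)")
  indefinite <- is.null(timeout) || timeout <= 0
  clock <- listener$clock
  deadline <- if (indefinite) Inf else clock$now() + timeout
  repeat {
    batch <- listener$source$poll()
    for (ev in batch) {
      r <- offer_event(listener, handlers, ev)
      if (!is.null(r)) return(r)
    }
    if (clock$now() >= deadline) return(timeout_sentinel())
    if (length(batch) == 0L)
      clock$sleep(min(listener$poll_interval,
                      max(deadline - clock$now(), 0)))
  }
}

#' Wait for one of a set of keys
#'
#' Returns when one of `keys` is pressed; other keys are ignored. The result
#' carries the event timestamp as attribute `"time"` (seconds on the session
#' clock), which the trial harness uses for exact reaction times.
#'
#' @param listener An [event_listener()].
#' @param keys Non-empty character vector of key identifiers.
#' @param timeout Seconds, or `NULL` to wait indefinitely.
#' @return The pressed key (with attribute `"time"`), or the timeout
#'   sentinel.
#' @export
wait_for_keys <- function(listener, keys, timeout = NULL) {
  if (!is.character(keys) || length(keys) == 0L)
    abort_invalid("keys must be a non-empty character vector")
  handler <- function(ev) {
    if (identical(ev$kind, "key_down") && ev$key %in% keys)
      structure(ev$key, time = ev$time)
    else NULL
  }
  listen(listener, list(handler), timeout)
}

#' Wait for a unicode character
#'
#' Returns the character of the first unicode-character event not in
#' `ignored` — the method of choice for text input, since it yields the
#' character itself rather than an abstract key code.
#'
#' @param listener An [event_listener()].
#' @param ignored Character vector of characters to skip.
#' @param timeout Seconds, or `NULL` to wait indefinitely.
#' @return The character (with attribute `"time"`), or the timeout sentinel.
#' @export
wait_for_unicode_char <- function(listener, ignored = character(0),
                                  timeout = NULL) {
  handler <- function(ev) {
    if (identical(ev$kind, "unicode_char") && !(ev$char %in% ignored))
      structure(ev$char, time = ev$time)
    else NULL
  }
  listen(listener, list(handler), timeout)
}

#' Wait for a fixed duration
#'
#' Waits at least `duration` seconds on the listener's clock (the ITI wait).
#' Events arriving during the wait are still offered to the permanent
#' handlers — so a global abort key keeps working — but their results are
#' discarded; a quit event still aborts.
#'
#' @param listener An [event_listener()].
#' @param duration Seconds (>= 0).
#' @return `NULL`, invisibly, after the duration has elapsed.
#' @export
wait_for_seconds <- function(listener, duration) {
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration < 0)
    abort_invalid("duration must be a single number >= 0")
  clock <- listener$clock
  deadline <- clock$now() + duration
  repeat {
    batch <- listener$source$poll()
    for (ev in batch) offer_event(listener, list(), ev)  # results discarded
    remaining <- deadline - clock$now()
    if (remaining <= 0) return(invisible(NULL))
    if (length(batch) == 0L)
      clock$sleep(min(listener$poll_interval, remaining))
  }
}

#' Build a mouse-dispatch handler from a layout trace
#'
#' Turns the mouse areas registered during [compose()] into a handler for
#' [listen()]: for every mouse event whose position falls inside an assigned
#' rect (half-open containment, so the right/bottom edges are outside), the
#' topmost — i.e. last-composed — matching area's callback is invoked with
#' `(event, rect)`. The handler always returns `NULL`: dispatching never ends
#' a wait by itself.
#'
#' @param trace A layout trace whose tree contained [mouse_area()] nodes.
#' @return A handler function.
#' @export
mouse_dispatch_handler <- function(trace) {
  if (!inherits(trace, "sc_layout_trace"))
    abort_invalid("trace must be a layout trace")
  areas <- trace$mouse_areas
  function(ev) {
    if (!ev$kind %in% c("mouse_down", "mouse_up", "mouse_move")) return(NULL)
    for (a in rev(areas)) {  # last-composed area is topmost
      if (rect_contains_point(a$rect, ev$pos[1], ev$pos[2])) {
        a$callback(ev, a$rect)
        return(NULL)
      }
    }
    NULL
  }
}
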