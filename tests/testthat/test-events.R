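# Event listening against the injectable clock and scripted source: handler
# chains, timeouts, waiting primitives, mouse dispatch.

make_listener <- function(events = list(), handlers = list(),
                          start = 0, poll_interval = 0.001) {
  clock <- simulated_clock(start)
  src <- scripted_event_source(events, clock)
  list(listener = event_listener(src, clock, handlers, poll_interval),
       clock = clock)
}

test_that("listen returns the first non-NULL handler result", {
  f <- make_listener(list(key_down_event("K", 0)))
  got <- listen(f$listener, list(function(ev)
    if (ev$kind == "key_down") ev$key else NULL))
  expect_equal(got, "K")
})

test_that("handler order decides: permanent before call-site, first wins", {
  ev <- list(key_down_event("X", 0))
  # two call-site handlers both matching: the first one wins
  f <- make_listener(ev)
  got <- listen(f$listener,
                list(function(e) "first", function(e) "second"))
  expect_equal(got, "first")
  # the permanent handler sees the event before any call-site handler
  f2 <- make_listener(ev, handlers = list(function(e) "permanent"))
  got2 <- listen(f2$listener, list(function(e) "call-site"))
  expect_equal(got2, "permanent")
})

test_that("listen times out within [T, T + poll_interval] of simulated time", {
  set.seed(23)
  for (i in 1:50) {
    timeout <- runif(1, 0.01, 2)
    poll <- runif(1, 0.0005, 0.05)
    f <- make_listener(poll_interval = poll)
    r <- listen(f$listener, list(function(e) "never"), timeout = timeout)
    expect_true(is_timeout(r))
    elapsed <- f$clock$now()
    expect_gte(elapsed, timeout)
    expect_lte(elapsed, timeout + poll + 1e-9)
  }
})

test_that("listen requires at least one handler and a valid listener", {
  f <- make_listener()
  expect_error(listen(f$listener, list()), class = "sc_invalid_argument")
  expect_error(listen("x", list(function(e) 1)),
               class = "sc_invalid_argument")
})

test_that("every event is offered at most once within a listen call", {
  seen <- new.env(); seen$keys <- character(0)
  events <- list(key_down_event("A", 0), key_down_event("B", 0),
                 key_down_event("C", 0.01))
  f <- make_listener(events)
  counter <- function(ev) {
    seen$keys <- c(seen$keys, ev$key)
    if (ev$key == "C") "done" else NULL
  }
  expect_equal(listen(f$listener, list(counter)), "done")
  expect_equal(seen$keys, c("A", "B", "C"))
})

test_that("wait_for_keys returns the first member key and skips others", {
  f <- make_listener(list(key_down_event("J", 0.2)))
  expect_equal(as.character(wait_for_keys(f$listener, c("F", "J"))), "J")

  f2 <- make_listener(list(key_down_event("Q", 0.1),
                           key_down_event("F", 0.3)))
  got <- wait_for_keys(f2$listener, "F")
  expect_equal(as.character(got), "F")
  expect_equal(attr(got, "time"), 0.3)

  f3 <- make_listener()
  expect_true(is_timeout(wait_for_keys(f3$listener, "F", timeout = 1)))
  expect_error(wait_for_keys(f3$listener, character(0)),
               class = "sc_invalid_argument")
})

test_that("wait_for_unicode_char returns chars and honors the ignore set", {
  f <- make_listener(list(unicode_char_event("a", 0)))
  expect_equal(as.character(wait_for_unicode_char(f$listener)), "a")
  f2 <- make_listener(list(unicode_char_event(" ", 0),
                           unicode_char_event("b", 0.1)))
  expect_equal(as.character(wait_for_unicode_char(f2$listener, ignored = " ")),
               "b")
  f3 <- make_listener()
  expect_true(is_timeout(wait_for_unicode_char(f3$listener, timeout = 0.5)))
})

test_that("wait_for_seconds advances the clock and feeds permanent handlers", {
  f <- make_listener()
  wait_for_seconds(f$listener, 0)
  expect_equal(f$clock$now(), 0)
  wait_for_seconds(f$listener, 2)
  expect_gte(f$clock$now(), 2)

  # permanent handlers still see events; their results are discarded
  seen <- new.env(); seen$n <- 0L
  f2 <- make_listener(list(key_down_event("A", 0.5)),
                      handlers = list(function(e) {
                        seen$n <- seen$n + 1L
                        "result-to-discard"
                      }))
  wait_for_seconds(f2$listener, 1)
  expect_equal(seen$n, 1L)
  expect_gte(f2$clock$now(), 1)
  expect_error(wait_for_seconds(f2$listener, -1),
               class = "sc_invalid_argument")
})

test_that("a quit event raises user-abort after permanent handlers see it", {
  seen <- new.env(); seen$quit <- FALSE
  f <- make_listener(list(quit_event(0.1)),
                     handlers = list(function(e) {
                       if (e$kind == "quit") seen$quit <- TRUE
                       NULL
                     }))
  expect_error(wait_for_keys(f$listener, "F"), class = "sc_user_abort")
  expect_true(seen$quit)
  # also during a plain wait
  f2 <- make_listener(list(quit_event(0.5)))
  expect_error(wait_for_seconds(f2$listener, 2), class = "sc_user_abort")
})

test_that("mouse dispatch hits the topmost area with half-open containment", {
  hits <- new.env(); hits$log <- character(0)
  cb <- function(id) function(ev, r) hits$log <- c(hits$log, id)
  tree <- overlay(
    mouse_area(cb("bottom"), fill("#FF0000")),
    lin_layout("h", mouse_area(cb("left")), mouse_area(cb("right")))
  )
  tr <- compose_to_buffer(tree, 20, 10)$trace
  h <- mouse_dispatch_handler(tr)

  expect_null(h(mouse_event("mouse_down", 5, 5, time = 0)))
  expect_equal(hits$log, "left")  # topmost (last-composed) wins over bottom

  hits$log <- character(0)
  h(mouse_event("mouse_down", 15, 5, time = 0))
  expect_equal(hits$log, "right")

  # half-open: a click at the exact right/bottom edge is outside everything
  hits$log <- character(0)
  h(mouse_event("mouse_down", 20, 10, time = 0))
  expect_equal(hits$log, character(0))

  # non-mouse events are ignored
  expect_null(h(key_down_event("F", 0)))
  expect_equal(hits$log, character(0))
})

test_that("overlapping mouse areas: composing order decides, both orders", {
  for (topmost_first in c(FALSE, TRUE)) {
    hits <- new.env(); hits$log <- character(0)
    cb <- function(id) function(ev, r) hits$log <- c(hits$log, id)
    kids <- list(mouse_area(cb("a"), fill("#111111")),
                 mouse_area(cb("b"), fill("#222222")))
    if (topmost_first) kids <- rev(kids)
    tr <- compose_to_buffer(do.call(overlay, kids), 10, 10)$trace
    mouse_dispatch_handler(tr)(mouse_event("mouse_down", 3, 3, time = 0))
    expect_equal(hits$log, if (topmost_first) "a" else "b")
  }
})

test_that("scripted sources release events by timestamp, in order, once", {
  clock <- simulated_clock()
  src <- scripted_event_source(list(key_down_event("B", 0.2),
                                    key_down_event("A", 0.1)), clock)
  expect_length(src$poll(), 0)
  clock$advance(0.15)
  batch <- src$poll()
  expect_length(batch, 1)
  expect_equal(batch[[1]]$key, "A")  # sorted by time despite input order
  clock$advance(0.1)
  expect_equal(src$poll()[[1]]$key, "B")
  expect_length(src$poll(), 0)
})

test_that("event scripts round-trip through JSON lines", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"t": 0.5, "kind": "key_down", "key": "F"}',
    '{"t": 1.0, "kind": "unicode_char", "char": "x"}',
    '{"t": 1.5, "kind": "mouse_down", "x": 3, "y": 4}',
    '{"t": 2.0, "kind": "quit"}'
  ), path)
  evs <- read_event_script(path)
  expect_length(evs, 4)
  expect_equal(evs[[1]]$key, "F")
  expect_equal(evs[[2]]$char, "x")
  expect_equal(evs[[3]]$pos, c(3L, 4L))
  expect_equal(evs[[4]]$kind, "quit")
  expect_equal(vapply(evs, `[[`, 0, "time"), c(0.5, 1, 1.5, 2))
})
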