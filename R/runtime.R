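# Display/session helpers. One display context per process, created with
# display_init(). The headless backend presents frames into a digest log
# (optionally keeping full frames); the windowed backend pushes the raster
# to a grDevices device. Compose output is identical under both — the
# backend only decides what "presenting" means.

.runtime <- new.env(parent = emptyenv())
.runtime$context <- NULL

#' Initialize the display
#'
#' Creates the single display context of the process. With the headless
#' backend an off-screen presentation target and an empty frame log are
#' allocated; with the windowed backend a grDevices raster device is opened
#' (useful for demos; experiment timing guarantees are out of scope).
#'
#' @param resolution Integer `c(w, h)` in pixels.
#' @param fullscreen Request fullscreen (windowed backend only; advisory).
#' @param backend `"headless"` (default) or `"windowed"`.
#' @param keep_frames Headless only: also keep full frame copies in the log.
#' @return The display context (class `"sc_display_context"`), invisibly
#'   obtainable again via [display_context()].
#' @export
display_init <- function(resolution, fullscreen = FALSE,
                         backend = c("headless", "windowed"),
                         keep_frames = FALSE) {
  if (!is.null(.runtime$context))
    abort_state("display already initialized; call display_quit() first")
  if (!is.numeric(resolution) || length(resolution) != 2L ||
      anyNA(resolution) || any(resolution < 1) ||
      any(resolution != trunc(resolution)))
    abort_invalid("resolution must be two positive integers c(w, h)")
  backend <- match.arg(backend)
  ctx <- new.env(parent = emptyenv())
  ctx$resolution <- as.integer(resolution)
  ctx$fullscreen <- isTRUE(fullscreen)
  ctx$backend <- backend
  ctx$frame_log <- character(0)
  ctx$frames <- list()
  ctx$keep_frames <- isTRUE(keep_frames)
  if (backend == "windowed") {
    if (!interactive() && !capabilities("X11") && !capabilities("aqua"))
      sc_abort("sc_backend_error", "no display device available for the windowed backend")
    grDevices::dev.new(width = resolution[1] / 96,
                       height = resolution[2] / 96, noRStudioGD = TRUE)
    ctx$device <- grDevices::dev.cur()
  }
  class(ctx) <- "sc_display_context"
  .runtime$context <- ctx
  invisible(ctx)
}

#' Get the active display context
#'
#' @return The context created by [display_init()].
#' @export
display_context <- function() {
  if (is.null(.runtime$context))
    abort_state("display not initialized; call display_init() first")
  .runtime$context
}

#' Tear down the display
#'
#' Closes the window (if any) and clears the context so [display_init()] can
#' be called again. Safe to call when no context exists.
#'
#' @return `NULL`, invisibly.
#' @export
display_quit <- function() {
  ctx <- .runtime$context
  if (!is.null(ctx) && identical(ctx$backend, "windowed") &&
      !is.null(ctx$device))
    try(grDevices::dev.off(ctx$device), silent = TRUE)
  .runtime$context <- NULL
  invisible(NULL)
}

#' Present a composed buffer
#'
#' Presents `buffer` on the active display. The buffer must match the display
#' resolution exactly. Headless: the frame's content digest is appended to
#' the context's `frame_log` (and the full frame kept when the context was
#' created with `keep_frames = TRUE`).
#'
#' @param buffer A pixel buffer of the display's size.
#' @return `NULL`, invisibly.
#' @export
display_show <- function(buffer) {
  ctx <- display_context()
  if (!is_pixel_buffer(buffer)) abort_invalid("buffer must be a pixel buffer")
  if (!identical(buffer_size(buffer), ctx$resolution))
    abort_invalid(sprintf("buffer size %dx%d does not match display resolution %dx%d",
                          buffer$w, buffer$h,
                          ctx$resolution[1], ctx$resolution[2]))
  if (identical(ctx$backend, "windowed")) {
    grDevices::dev.set(ctx$device)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(buffer_pixels(buffer) / 255),
                          0, 0, 1, 1, interpolate = FALSE)
  }
  ctx$frame_log <- c(ctx$frame_log, buffer_digest(buffer))
  if (ctx$keep_frames)
    ctx$frames[[length(ctx$frames) + 1L]] <- buffer_pixels(buffer)
  invisible(NULL)
}

#' Blank colored surface
#'
#' Creates a pixel buffer filled with one color, sized to the display by
#' default — the canonical background for [compose()].
#'
#' @param color Fill color (hex string or triple).
#' @param size Optional `c(w, h)`; defaults to the display resolution (which
#'   then requires an initialized display).
#' @return A pixel buffer.
#' @export
empty_surface <- function(color, size = NULL) {
  if (is.null(size)) {
    if (is.null(.runtime$context))
      abort_state("no display context: pass an explicit size or call display_init()")
    size <- display_context()$resolution
  }
  if (!is.numeric(size) || length(size) != 2L)
    abort_invalid("size must be c(w, h)")
  pixel_buffer(size[1], size[2], color)
}

#' Show frames one after another
#'
#' Presents each frame in order, calling `proceed()` once after each frame;
#' `proceed` is expected to block until the subject advances (for example a
#' wait for the return key). A user-abort raised inside `proceed` stops the
#' show after the current frame and propagates.
#'
#' @param frames Non-empty list of pixel buffers (display-sized).
#' @param proceed Function of no arguments called after each frame.
#' @return `NULL`, invisibly.
#' @export
slide_show <- function(frames, proceed) {
  if (!is.list(frames) || length(frames) == 0L)
    abort_invalid("frames must be a non-empty list of pixel buffers")
  if (!is.function(proceed)) abort_invalid("proceed must be a function")
  for (f in frames) {
    display_show(f)
    proceed()
  }
  invisible(NULL)
}

#' Apply one typed character to a text-entry buffer
#'
#' The editing rule behind free-text input: backspace (U+0008) removes the
#' last character (a no-op on an empty buffer); carriage return or newline
#' finishes the entry (`done = TRUE`, text unchanged); any other printable
#' character (visible glyph or space) is appended; remaining control
#' characters are ignored.
#'
#' @param text Current buffer contents.
#' @param ch A single character (as delivered by [wait_for_unicode_char()]).
#' @return A list with `text` (updated string) and `done` (flag).
#' @examples
#' edit_buffer("ab", "c")     # "abc", not done
#' edit_buffer("ab", "\b")    # "a",   not done
#' edit_buffer("ab", "\r")    # "ab",  done
#' @export
edit_buffer <- function(text, ch) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    abort_invalid("text must be a single string")
  if (!is.character(ch) || length(ch) != 1L || nchar(ch) != 1L)
    abort_invalid("ch must be a single character")
  code <- utf8ToInt(ch)
  if (code == 8L) {  # backspace
    n <- nchar(text)
    return(list(text = if (n > 0L) substr(text, 1L, n - 1L) else text,
                done = FALSE))
  }
  if (code %in% c(10L, 13L))  # newline / carriage return
    return(list(text = text, done = TRUE))
  printable <- code == 32L || grepl("[[:graph:]]", ch)
  if (printable)
    return(list(text = paste0(text, ch), done = FALSE))
  list(text = text, done = FALSE)
}
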