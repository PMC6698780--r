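# LayoutTrace: the record of which rect every tree node received during a
# compose pass, in draw order. This is the headless test surface — layout
# questions ("is the offer box 80% of its cell?") are answered from the
# trace without looking at pixels.

#' @export
format.sc_layout_trace <- function(x, ...) {
  sprintf("<layout trace: %d nodes, %d mouse areas, target %dx%d>",
          length(x$entries), length(x$mouse_areas), x$size[1], x$size[2])
}

#' @export
print.sc_layout_trace <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Convert a layout trace to a data frame
#'
#' @param x A layout trace from [compose()].
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @return A data frame with columns `path`, `kind`, `x`, `y`, `w`, `h`, one
#'   row per composed node in draw order.
#' @export
as.data.frame.sc_layout_trace <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    path = vapply(x$entries, `[[`, "", "path"),
    kind = vapply(x$entries, `[[`, "", "kind"),
    x = vapply(x$entries, function(e) e$rect$x, 0L),
    y = vapply(x$entries, function(e) e$rect$y, 0L),
    w = vapply(x$entries, function(e) e$rect$w, 0L),
    h = vapply(x$entries, function(e) e$rect$h, 0L),
    stringsAsFactors = FALSE
  )
}

#' Look up the rect assigned to a node path
#'
#' Node paths name positions in the tree: `"/"` is the root, `"/2"` its
#' second child, `"/2/1"` that child's first child; grid cells use
#' `"/<row>.<col>"` segments.
#'
#' @param trace A layout trace.
#' @param path Node path string.
#' @return The assigned rect.
#' @export
trace_rect <- function(trace, path) {
  for (e in trace$entries) if (identical(e$path, path)) return(e$rect)
  abort_invalid(sprintf("no node at path %s in trace", path))
}

#' Select trace entries by element kind
#'
#' @param trace A layout trace.
#' @param kind Element kind, e.g. `"border"`, `"text"`.
#' @return The matching entries (list of `path`/`kind`/`rect` records) in
#'   draw order.
#' @export
trace_entries <- function(trace, kind = NULL) {
  if (is.null(kind)) return(trace$entries)
  Filter(function(e) identical(e$kind, kind), trace$entries)
}

# Parent path of "/a/b" is "/a"; parent of "/a" is "/"; grid-cell segments
# ("/1.2") behave like ordinary segments.
parent_path <- function(path) {
  if (identical(path, "/")) return(NA_character_)
  p <- sub("/[^/]+$", "", path)
  if (identical(p, "")) "/" else p
}

#' Check the containment invariant of a trace
#'
#' Verifies that every entry's rect is contained in its parent entry's rect.
#'
#' @param trace A layout trace.
#' @return `TRUE` if the invariant holds, otherwise `FALSE`.
#' @export
trace_containment_ok <- function(trace) {
  rects <- list()
  for (e in trace$entries) rects[[e$path]] <- e$rect
  for (e in trace$entries) {
    pp <- parent_path(e$path)
    if (is.na(pp)) next
    parent <- rects[[pp]]
    if (is.null(parent) || !rect_contains(parent, e$rect)) return(FALSE)
  }
  TRUE
}

#' Export a layout trace as JSON
#'
#' Writes the trace as a JSON array of `{path, kind, rect: [x, y, w, h]}`
#' objects in draw order — a stable text form for golden-trace regression
#' tests and the command-line renderer.
#'
#' @param trace A layout trace.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
trace_to_json <- function(trace, path = NULL) {
  items <- lapply(trace$entries, function(e)
    list(path = e$path, kind = e$kind,
         rect = c(e$rect$x, e$rect$y, e$rect$w, e$rect$h)))
  json <- jsonlite::toJSON(items, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}
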