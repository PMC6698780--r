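# The recursive compose pass: walks the render tree, assigns every node an
# integer pixel rect (the full target for the root), lets layouts subdivide,
# wrappers shrink, and primitives draw, and records a LayoutTrace entry per
# node in draw order. The pass is fully deterministic: the same tree composed
# onto a target of the same size yields byte-identical pixels and an
# identical trace.

#' Compose a render tree onto a pixel buffer
#'
#' @param root An element, a raw image, or `NULL` (draw nothing).
#' @param target A [pixel_buffer()] to draw into (mutated in place).
#' @return A layout trace: an object of class `"sc_layout_trace"` recording,
#'   in draw order, the rect assigned to every composed node, plus the mouse
#'   areas registered during the pass (see [mouse_dispatch_handler()]).
#' @examples
#' buf <- pixel_buffer(100, 50, "#FFFFFF")
#' tr <- compose(lin_layout("h", fill("#FF0000"), fill("#0000FF")), buf)
#' as.data.frame(tr)
#' @export
compose <- function(root, target) {
  if (!is_pixel_buffer(target)) abort_invalid("target must be a pixel buffer")
  ctx <- new.env(parent = emptyenv())
  ctx$entries <- list()
  ctx$mouse_areas <- list()
  root <- normalize_child(root)
  area <- rect(0, 0, target$w, target$h)
  if (!is.null(root)) compose_node(root, area, target, ctx, "/")
  structure(list(entries = ctx$entries, mouse_areas = ctx$mouse_areas,
                 size = c(target$w, target$h)),
            class = "sc_layout_trace")
}

#' Compose a tree headlessly into a fresh buffer
#'
#' Convenience wrapper: allocates a buffer of the given size and background,
#' composes into it, and returns both.
#'
#' @param root An element, raw image, or `NULL`.
#' @param w,h Target size in pixels.
#' @param background Background color (default white).
#' @return A list with components `buffer` and `trace`.
#' @export
compose_to_buffer <- function(root, w, h, background = "#FFFFFF") {
  buf <- pixel_buffer(w, h, background)
  trace <- compose(root, buf)
  list(buffer = buf, trace = trace)
}

child_path <- function(path, i) {
  if (identical(path, "/")) paste0("/", i) else paste0(path, "/", i)
}

record_entry <- function(ctx, path, kind, area) {
  ctx$entries[[length(ctx$entries) + 1L]] <-
    list(path = path, kind = kind, rect = area)
}

validate_node <- function(node, path) {
  if (!is_element(node) || is.null(node$kind))
    abort_compose("invalid node in tree", path)
  wrapper_kinds <- c("ll_item", "padding", "border", "fill",
                     "rectangle_shaper", "mouse_area")
  if (node$kind %in% wrapper_kinds && length(node$children) > 1L)
    abort_compose(sprintf("%s wrapper must have at most one child", node$kind),
                  path)
  primitive_kinds <- c("image", "text", "circle", "cross", "line")
  if (node$kind %in% primitive_kinds && length(node$children) > 0L)
    abort_compose(sprintf("%s primitive must not have children", node$kind),
                  path)
}

compose_node <- function(node, area, target, ctx, path) {
  validate_node(node, path)
  record_entry(ctx, path, node$kind, area)
  switch(node$kind,
    lin_layout = compose_lin_layout(node, area, target, ctx, path),
    ll_item = compose_single_child(node, area, target, ctx, path),
    grid_layout = compose_grid(node, area, target, ctx, path),
    overlay = {
      for (i in seq_along(node$children))
        compose_node(node$children[[i]], area, target, ctx, child_path(path, i))
    },
    padding = {
      inner <- inset_fractional(area, node$left, node$right,
                                node$top, node$bottom)
      compose_single_child(node, inner, target, ctx, path)
    },
    border = {
      draw_border(target, area, node$color, node$width)
      inner <- rect(area$x + node$width, area$y + node$width,
                    max(area$w - 2L * node$width, 0L),
                    max(area$h - 2L * node$width, 0L))
      compose_single_child(node, inner, target, ctx, path)
    },
    fill = {
      buffer_fill_rect(target, area, node$color)
      compose_single_child(node, area, target, ctx, path)
    },
    rectangle_shaper = {
      inner <- aspect_rect(node$prop_w, node$prop_h, area)
      compose_single_child(node, inner, target, ctx, path)
    },
    mouse_area = {
      ctx$mouse_areas[[length(ctx$mouse_areas) + 1L]] <-
        list(path = path, rect = area, callback = node$callback)
      compose_single_child(node, area, target, ctx, path)
    },
    image = draw_image(node, area, target),
    text = draw_text(node, area, target),
    circle = ,
    cross = ,
    line = draw_primitive(node, area, target),
    abort_compose(sprintf("unknown element kind '%s'", node$kind), path)
  )
  invisible(NULL)
}

compose_single_child <- function(node, area, target, ctx, path) {
  if (length(node$children) == 1L)
    compose_node(node$children[[1L]], area, target, ctx, child_path(path, 1L))
}

compose_lin_layout <- function(node, area, target, ctx, path) {
  n <- length(node$children)
  if (n == 0L) return(invisible(NULL))
  weights <- vapply(node$children, function(c) c$relative_size, 0)
  if (sum(weights) <= 0)
    abort_compose("linear layout weights are all zero", path)
  horizontal <- node$orientation == "horizontal"
  segments <- split_interval(if (horizontal) area$w else area$h, weights)
  offsets <- c(0L, cumsum(segments))
  for (i in seq_len(n)) {
    slot <- if (horizontal)
      rect(area$x + offsets[i], area$y, segments[i], area$h)
    else
      rect(area$x, area$y + offsets[i], area$w, segments[i])
    compose_node(node$children[[i]], slot, target, ctx, child_path(path, i))
  }
}

compose_grid <- function(node, area, target, ctx, path) {
  nrows <- length(node$rows)
  ncols <- max(vapply(node$rows, length, 1L))
  rp <- node$row_proportions %||% rep(1, nrows)
  cp <- node$col_proportions %||% rep(1, ncols)
  heights <- split_interval(area$h, rp)
  widths <- split_interval(area$w, cp)
  yoff <- c(0L, cumsum(heights))
  xoff <- c(0L, cumsum(widths))
  k <- 0L
  for (i in seq_len(nrows)) {
    row <- node$rows[[i]]
    for (j in seq_len(ncols)) {
      cell <- if (j <= length(row)) row[[j]] else NULL
      if (is.null(cell)) next  # empty cell: area untouched, no trace entry
      k <- k + 1L
      slot <- rect(area$x + xoff[j], area$y + yoff[i], widths[j], heights[i])
      compose_node(cell, slot, target, ctx,
                   paste0(child_path(path, i), ".", j))
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
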