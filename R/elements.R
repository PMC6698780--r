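# Element constructors for the render tree. Elements are pure descriptions
# (rendering instructions), never pixel data: a list with a `kind` field,
# kind-specific attributes, and a `children` list. Layouts divide their space
# among any number of children, wrappers modify the area of exactly one
# optional child, primitives draw and have no children.

new_element <- function(kind, ..., children = list()) {
  structure(list(kind = kind, ..., children = children),
            class = c(paste0("sc_", kind), "sc_element"))
}

is_element <- function(x) inherits(x, "sc_element")

# Raw images are accepted wherever an element is: h x w x 3 arrays, 2D
# grayscale matrices, and pixel buffers all auto-wrap into image elements.
is_imageish <- function(x) {
  is_pixel_buffer(x) ||
    (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L) ||
    (is.matrix(x) && is.numeric(x))
}

as_image_array <- function(x) {
  if (is_pixel_buffer(x)) return(buffer_pixels(x))
  if (is.matrix(x)) {
    x <- pmin(pmax(x, 0), 255)
    return(array(rep(as.integer(round_half_up(x)), 3L), dim = c(dim(x), 3L)))
  }
  x
}

#' Normalize a raw child into an element
#'
#' Applies the auto-wrapping rules of the composer: a raw image (array,
#' matrix, or pixel buffer) becomes an [image_element()] with default
#' settings; an element passes through unchanged; in a linear-layout context
#' any child that is not already an [ll_item()] is wrapped in one with
#' relative size 1; `NULL` becomes an empty spacer slot (linear layout) or an
#' empty cell (grid). Raw strings are deliberately *not* auto-wrapped into
#' text: only images auto-wrap.
#'
#' @param raw An element, a raw image, or `NULL`.
#' @param context One of `"lin_layout"`, `"grid"`, `"generic"`.
#' @return An element, or `NULL` for an absent grid cell / root.
#' @export
normalize_child <- function(raw, context = "generic") {
  if (is.null(raw)) {
    if (context == "lin_layout") return(ll_item(1))
    return(NULL)
  }
  if (is_imageish(raw)) raw <- image_element(raw)
  if (!is_element(raw))
    abort_invalid(sprintf(
      "unsupported child of type %s (only elements and images are accepted)",
      paste(class(raw), collapse = "/")))
  if (context == "lin_layout" && raw$kind != "ll_item")
    return(ll_item(1, raw))
  raw
}

check_scalar_number <- function(x, what, min = -Inf, strict_min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("%s must be a single finite number", what))
  if (!is.null(strict_min) && x <= strict_min)
    abort_invalid(sprintf("%s must be > %s", what, strict_min))
  if (x < min)
    abort_invalid(sprintf("%s must be >= %s", what, min))
  invisible(x)
}

#' Linear layout
#'
#' Arranges its children in a horizontal or vertical line. By default the
#' available space is split equally; wrap a child in [ll_item()] to change
#' its share or pass `NULL` for an empty spacer cell.
#'
#' @param orientation `"horizontal"`/`"h"` or `"vertical"`/`"v"`.
#' @param ... Children: elements, raw images, [ll_item()]s, or `NULL`
#'   spacers. Non-`ll_item` children are wrapped in `ll_item(1, child)`.
#' @return A layout element.
#' @examples
#' lin_layout("h", text_element("left"), text_element("right"))
#' lin_layout("v", ll_item(2, text_element("big")), ll_item(1, NULL))
#' @export
lin_layout <- function(orientation, ...) {
  orientation <- match.arg(orientation, c("horizontal", "vertical", "h", "v"))
  orientation <- c(h = "horizontal", v = "vertical",
                   horizontal = "horizontal", vertical = "vertical")[[orientation]]
  children <- lapply(list(...), normalize_child, context = "lin_layout")
  new_element("lin_layout", orientation = orientation, children = children)
}

#' Linear layout item
#'
#' A slot of a [lin_layout()] carrying a relative size weight. A slot with no
#' child is an empty spacer: it consumes its share of the space but draws
#' nothing.
#'
#' @param relative_size Non-negative weight (default 1).
#' @param child Optional element or raw image.
#' @return An `ll_item` element.
#' @export
ll_item <- function(relative_size = 1, child = NULL) {
  check_scalar_number(relative_size, "relative_size", min = 0)
  child <- normalize_child(child)
  new_element("ll_item", relative_size = relative_size,
              children = if (is.null(child)) list() else list(child))
}

#' Grid layout
#'
#' Arranges children on a grid. `rows` is a list of rows, each a list of
#' cells; `NULL` (or a short row) leaves a cell empty. Row heights and column
#' widths are split proportionally to `row_proportions` / `col_proportions`
#' (equal shares when omitted); crucially they depend only on these
#' proportions and the outer rect, never on cell content. The column count is
#' the length of the longest row; ragged rows are padded with empty cells on
#' the right.
#'
#' @param rows List of lists of optional children.
#' @param row_proportions,col_proportions Optional non-negative weight
#'   vectors matching the number of rows / columns.
#' @return A layout element.
#' @export
grid_layout <- function(rows, row_proportions = NULL, col_proportions = NULL) {
  if (!is.list(rows) || length(rows) == 0L || !all(vapply(rows, is.list, TRUE)))
    abort_invalid("rows must be a non-empty list of lists")
  ncols <- max(vapply(rows, length, 1L))
  if (ncols == 0L) abort_invalid("grid must have at least one column")
  if (!is.null(row_proportions) && length(row_proportions) != length(rows))
    abort_invalid("row_proportions must have one entry per row")
  if (!is.null(col_proportions) && length(col_proportions) != ncols)
    abort_invalid("col_proportions must have one entry per column")
  cells <- lapply(rows, function(r) {
    r <- lapply(r, normalize_child, context = "grid")
    length(r) <- ncols  # pad ragged rows with empty cells on the right
    r
  })
  new_element("grid_layout", rows = cells,
              row_proportions = row_proportions,
              col_proportions = col_proportions)
}

#' Overlay
#'
#' Draws its children on top of each other: every child is given the full
#' area, and later children are drawn over earlier ones (opaque draw order).
#'
#' @param ... Children (elements or raw images).
#' @return A layout element.
#' @export
overlay <- function(...) {
  children <- lapply(list(...), normalize_child)
  if (any(vapply(children, is.null, TRUE)))
    abort_invalid("overlay children must not be NULL")
  new_element("overlay", children = children)
}

#' Padding wrapper
#'
#' Insets the child's area by per-side fractions of the available width and
#' height. Fractions (not absolute pixels) keep screens resolution
#' independent.
#'
#' @param left,right,top,bottom Fractions in `[0, 1)`;
#'   `left + right < 1`, `top + bottom < 1`.
#' @param child Optional element or raw image.
#' @return A wrapper element.
#' @seealso [padding_scale()] for the symmetric "scale to f" variant.
#' @export
padding <- function(left = 0, right = 0, top = 0, bottom = 0, child = NULL) {
  fr <- c(left, right, top, bottom)
  if (!is.numeric(fr) || anyNA(fr) || any(fr < 0) || any(fr >= 1) ||
      left + right >= 1 || top + bottom >= 1)
    abort_invalid("padding fractions must lie in [0, 1) and opposing sides must sum to < 1")
  child <- normalize_child(child)
  new_element("padding", left = left, right = right, top = top,
              bottom = bottom,
              children = if (is.null(child)) list() else list(child))
}

#' Symmetric padding from a scale factor
#'
#' `padding_scale(0.8, x)` shrinks the child's area to 80% of the available
#' space, centered: every side is padded by `(1 - f) / 2`.
#'
#' @param f Scale factor in `(0, 1]`.
#' @param child Optional element or raw image.
#' @return A wrapper element.
#' @export
padding_scale <- function(f, child = NULL) {
  check_scalar_number(f, "scale factor", strict_min = 0)
  if (f > 1) abort_invalid("scale factor must be <= 1")
  side <- (1 - f) / 2
  padding(side, side, side, side, child)
}

#' Border wrapper
#'
#' Draws a rectangular stroke of the given width just inside the edges of the
#' assigned area; the child (if any) is composed into the area inset by the
#' stroke width on every side, so child rects stay contained in the parent.
#'
#' @param child Optional element or raw image.
#' @param color Stroke color (default black).
#' @param width Stroke width in pixels (>= 1, default 1).
#' @return A wrapper element.
#' @export
border <- function(child = NULL, color = "#000000", width = 1) {
  check_scalar_number(width, "border width", min = 1)
  if (width != trunc(width)) abort_invalid("border width must be an integer")
  child <- normalize_child(child)
  new_element("border", color = parse_color(color), width = as.integer(width),
              children = if (is.null(child)) list() else list(child))
}

#' Fill wrapper / rectangle primitive
#'
#' Fills the assigned area with a solid color, then composes the child (if
#' any) into the same area. With no child this *is* the rectangle primitive.
#'
#' @param color Fill color.
#' @param child Optional element or raw image.
#' @return An element.
#' @export
fill <- function(color, child = NULL) {
  child <- normalize_child(child)
  new_element("fill", color = parse_color(color),
              children = if (is.null(child)) list() else list(child))
}

#' Rectangle shaper wrapper
#'
#' Reduces the available area to the biggest rectangle with the given side
#' proportions (default 1:1, i.e. the largest centered square) and composes
#' the child into it.
#'
#' @param prop_w,prop_h Positive side proportions.
#' @param child Optional element or raw image.
#' @return A wrapper element.
#' @export
rectangle_shaper <- function(prop_w = 1, prop_h = 1, child = NULL) {
  check_scalar_number(prop_w, "prop_w", strict_min = 0)
  check_scalar_number(prop_h, "prop_h", strict_min = 0)
  child <- normalize_child(child)
  new_element("rectangle_shaper", prop_w = prop_w, prop_h = prop_h,
              children = if (is.null(child)) list() else list(child))
}

#' Image element
#'
#' Wraps a raster image (an `h x w x 3` array with values 0-255, a 2D
#' grayscale matrix, or a pixel buffer) for use in the tree. Images have a
#' native resolution, so by default they are scaled *down* to the biggest
#' rectangle that fits the available space without distortion, and centered
#' but never upscaled when the space is larger than the image. Raw images
#' placed in a tree are wrapped automatically with these defaults; construct
#' explicitly to change them.
#'
#' @param pixels The source image.
#' @param allow_upscale Permit enlarging beyond native size (default `FALSE`).
#' @param smooth_scale Area-averaging scaling (default) vs nearest-neighbor.
#' @return A primitive element.
#' @export
image_element <- function(pixels, allow_upscale = FALSE, smooth_scale = TRUE) {
  if (!is_imageish(pixels)) abort_invalid("pixels must be an image array, matrix, or pixel buffer")
  arr <- as_image_array(pixels)
  if (any(dim(arr)[1:2] < 1L)) abort_invalid("image must be at least 1x1")
  new_element("image", pixels = arr,
              allow_upscale = isTRUE(allow_upscale),
              smooth_scale = isTRUE(smooth_scale))
}

#' Mouse area wrapper
#'
#' Gives all its space to its child and registers a callback for mouse events
#' that fall inside the area it was assigned during compose. The callback is
#' invoked as `callback(event, rect)` by the handler returned from
#' [mouse_dispatch_handler()]. When composed areas overlap, the topmost
#' (last-composed) area wins.
#'
#' @param callback Function of `(event, rect)`.
#' @param child Optional element or raw image.
#' @return A wrapper element.
#' @export
mouse_area <- function(callback, child = NULL) {
  if (!is.function(callback)) abort_invalid("callback must be a function")
  child <- normalize_child(child)
  new_element("mouse_area", callback = callback,
              children = if (is.null(child)) list() else list(child))
}

#' Text primitive
#'
#' Renders (possibly multi-line) text into the assigned area. The line block
#' is centered vertically; horizontal placement follows `align`. Text is
#' never rescaled to fit: content exceeding the area is clipped.
#'
#' @param content The string to draw; `"\n"` separates lines.
#' @param font_size Font size in points (> 0, default 32).
#' @param bold Bold face (default `FALSE`).
#' @param color Text color (default black).
#' @param align `"left"`, `"center"` (default), or `"right"`.
#' @return A primitive element.
#' @export
text_element <- function(content, font_size = 32, bold = FALSE,
                         color = "#000000", align = "center") {
  if (!is.character(content) || length(content) != 1L || is.na(content))
    abort_invalid("content must be a single string")
  check_scalar_number(font_size, "font_size", strict_min = 0)
  align <- match.arg(align, c("left", "center", "right"))
  new_element("text", content = content, font_size = font_size,
              bold = isTRUE(bold), color = parse_color(color), align = align)
}

#' Circle primitive
#'
#' Draws the largest centered circle that fits the assigned area (diameter =
#' `min(w, h)`), filled by default or as a ring.
#'
#' @param color Color.
#' @param filled Filled disk (default) or ring.
#' @param stroke Ring width in pixels (>= 1) when `filled = FALSE`.
#' @return A primitive element.
#' @export
circle <- function(color = "#000000", filled = TRUE, stroke = 1) {
  check_scalar_number(stroke, "stroke", min = 1)
  new_element("circle", color = parse_color(color), filled = isTRUE(filled),
              stroke = as.integer(stroke))
}

#' Cross primitive
#'
#' Two centered strokes spanning the full width and height of the assigned
#' area (a plus sign; the usual fixation cross).
#'
#' @param color Color.
#' @param stroke Stroke width in pixels (>= 1, default 1).
#' @return A primitive element.
#' @export
cross <- function(color = "#000000", stroke = 1) {
  check_scalar_number(stroke, "stroke", min = 1)
  new_element("cross", color = parse_color(color), stroke = as.integer(stroke))
}

#' Line primitive
#'
#' A centered horizontal or vertical stroke spanning the assigned area along
#' its orientation.
#'
#' @param orientation `"horizontal"`/`"h"` or `"vertical"`/`"v"`.
#' @param color Color.
#' @param stroke Stroke width in pixels (>= 1, default 1).
#' @return A primitive element.
#' @export
line_element <- function(orientation, color = "#000000", stroke = 1) {
  orientation <- match.arg(orientation, c("horizontal", "vertical", "h", "v"))
  orientation <- c(h = "horizontal", v = "vertical",
                   horizontal = "horizontal", vertical = "vertical")[[orientation]]
  check_scalar_number(stroke, "stroke", min = 1)
  new_element("line", orientation = orientation, color = parse_color(color),
              stroke = as.integer(stroke))
}

#' @export
format.sc_element <- function(x, ...) {
  sprintf("<%s element, %d child%s>", x$kind, length(x$children),
          if (length(x$children) == 1L) "" else "ren")
}

#' @export
print.sc_element <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
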