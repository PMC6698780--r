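# Primitive drawing: shapes, images, and headless text rendering.
#
# Text uses a synthetic fixed-advance font so that pixel output and layout
# metrics are identical on every platform: glyph advance = ceil(0.6 * size),
# line height = round(1.2 * size). Glyphs are rendered as solid blocks (ink
# rectangles) — the goal is deterministic, testable geometry, not
# typographic fidelity.

#' Headless text metrics
#'
#' The fixed-advance metrics used by the deterministic text renderer.
#'
#' @param font_size Font size in points.
#' @return A list with `advance` (horizontal advance per glyph, pixels) and
#'   `line_height` (pixels).
#' @export
text_metrics <- function(font_size) {
  check_scalar_number(font_size, "font_size", strict_min = 0)
  list(advance = as.integer(ceiling(0.6 * font_size)),
       line_height = as.integer(round_half_up(1.2 * font_size)))
}

#' Measure a (possibly multi-line) string under the headless font
#'
#' @param content The string; `"\n"` separates lines.
#' @param font_size Font size in points.
#' @return Integer `c(w, h)` of the rendered block in pixels.
#' @export
measure_text <- function(content, font_size) {
  m <- text_metrics(font_size)
  lines <- split_lines(content)
  c(max(nchar(lines), 0L) * m$advance, length(lines) * m$line_height)
}

split_lines <- function(content) {
  if (identical(content, "")) return(character(0))
  strsplit(content, "\n", fixed = TRUE)[[1L]]
}

intersect_rects <- function(a, b) {
  x0 <- max(a$x, b$x); y0 <- max(a$y, b$y)
  x1 <- min(a$x + a$w, b$x + b$w); y1 <- min(a$y + a$h, b$y + b$h)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  rect(x0, y0, x1 - x0, y1 - y0)
}

# Fill `r` clipped against `clip` (used for glyph ink and strokes that may
# overflow their area).
fill_clipped <- function(target, r, clip, color) {
  ri <- intersect_rects(r, clip)
  if (!is.null(ri)) buffer_fill_rect(target, ri, color)
}

draw_text <- function(node, area, target) {
  lines <- split_lines(node$content)
  if (length(lines) == 0L || area$w <= 0L || area$h <= 0L)
    return(invisible(NULL))
  m <- text_metrics(node$font_size)
  glyph_h <- as.integer(round_half_up(node$font_size))
  block_h <- length(lines) * m$line_height
  top <- area$y + center_offset(area$h, block_h)
  # ink is narrower than the advance so adjacent glyphs stay distinct;
  # bold fills the full advance
  ink_w <- if (node$bold) m$advance else max(m$advance - 1L, 1L)
  for (li in seq_along(lines)) {
    line <- lines[[li]]
    nch <- nchar(line)
    if (nch == 0L) next
    line_w <- nch * m$advance
    x0 <- switch(node$align,
      left = area$x,
      center = area$x + center_offset(area$w, line_w),
      right = area$x + area$w - line_w)
    y0 <- top + (li - 1L) * m$line_height + center_offset(m$line_height, glyph_h)
    chars <- strsplit(line, "", fixed = TRUE)[[1L]]
    for (ci in seq_len(nch)) {
      if (chars[ci] == " ") next
      fill_clipped(target,
                   rect(x0 + (ci - 1L) * m$advance, y0, ink_w, glyph_h),
                   area, node$color)
    }
  }
  invisible(NULL)
}

draw_image <- function(node, area, target) {
  d <- dim(node$pixels)
  dest <- fit_rect(d[2L], d[1L], area, allow_upscale = node$allow_upscale)
  if (dest$w > 0L && dest$h > 0L)
    buffer_blit(target, node$pixels, dest, smooth = node$smooth_scale)
  invisible(NULL)
}

draw_border <- function(target, area, color, width) {
  if (area$w <= 0L || area$h <= 0L) return(invisible(NULL))
  w <- min(width, area$w, area$h)
  buffer_fill_rect(target, rect(area$x, area$y, area$w, w), color)            # top
  buffer_fill_rect(target, rect(area$x, area$y + area$h - w, area$w, w), color) # bottom
  buffer_fill_rect(target, rect(area$x, area$y, w, area$h), color)            # left
  buffer_fill_rect(target, rect(area$x + area$w - w, area$y, w, area$h), color) # right
  invisible(NULL)
}

draw_primitive <- function(node, area, target) {
  if (area$w <= 0L || area$h <= 0L) return(invisible(NULL))
  switch(node$kind,
    circle = {
      d <- min(area$w, area$h)
      buffer_draw_circle(target,
                         cx = area$x + area$w / 2,
                         cy = area$y + area$h / 2,
                         radius = d / 2, color = node$color,
                         filled = node$filled, stroke = node$stroke)
    },
    cross = {
      s <- node$stroke
      fill_clipped(target,
                   rect(area$x, area$y + center_offset(area$h, s), area$w, s),
                   area, node$color)
      fill_clipped(target,
                   rect(area$x + center_offset(area$w, s), area$y, s, area$h),
                   area, node$color)
    },
    line = {
      s <- node$stroke
      if (node$orientation == "horizontal")
        fill_clipped(target,
                     rect(area$x, area$y + center_offset(area$h, s), area$w, s),
                     area, node$color)
      else
        fill_clipped(target,
                     rect(area$x + center_offset(area$w, s), area$y, s, area$h),
                     area, node$color)
    })
  invisible(NULL)
}
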