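# PixelBuffer: a mutable 2D RGB raster. Pixels are stored as an
# h x w x 3 integer array (0-255) inside an environment so that drawing
# operations mutate in place, mirroring how a real drawing surface behaves.
# Row 1 is the top scanline; buffer_pixel(buf, x, y) uses the same
# 0-based, top-left-origin convention as rects.
#
# All drawing is opaque (no alpha): later draws overwrite earlier ones,
# which is exactly the overlay draw-order semantics the composer needs.

#' Create a pixel buffer
#'
#' Allocates a `w` by `h` RGB raster filled with `fill`. This is the drawing
#' surface that [compose()] renders into; it is deliberately an in-memory
#' object so screens can be rendered and inspected without any display.
#'
#' @param w,h Positive integer dimensions in pixels.
#' @param fill Background color (anything [parse_color()] accepts).
#' @return An object of class `"sc_pixel_buffer"`.
#' @examples
#' buf <- pixel_buffer(64, 48, "#FFFFFF")
#' buffer_size(buf)
#' @export
pixel_buffer <- function(w, h, fill = "#000000") {
  if (!is.numeric(w) || !is.numeric(h) || length(w) != 1L || length(h) != 1L ||
      !is.finite(w) || !is.finite(h) || w < 1 || h < 1 ||
      w != trunc(w) || h != trunc(h))
    abort_invalid("buffer dimensions must be positive integers")
  color <- parse_color(fill)
  env <- new.env(parent = emptyenv())
  env$pixels <- array(rep(as.integer(color), each = h * w),
                      dim = c(h, w, 3L))
  env$w <- as.integer(w)
  env$h <- as.integer(h)
  class(env) <- "sc_pixel_buffer"
  env
}

is_pixel_buffer <- function(x) inherits(x, "sc_pixel_buffer")

#' Buffer dimensions
#'
#' @param buf A pixel buffer.
#' @return Integer vector `c(w, h)`.
#' @export
buffer_size <- function(buf) {
  if (!is_pixel_buffer(buf)) abort_invalid("not a pixel buffer")
  c(buf$w, buf$h)
}

#' Read the pixel array of a buffer
#'
#' @param buf A pixel buffer.
#' @return The `h x w x 3` integer array (a copy; mutating it does not touch
#'   the buffer).
#' @export
buffer_pixels <- function(buf) {
  if (!is_pixel_buffer(buf)) abort_invalid("not a pixel buffer")
  buf$pixels
}

#' Read one pixel
#'
#' @param buf A pixel buffer.
#' @param x,y 0-based pixel coordinates (top-left origin).
#' @return Integer `c(r, g, b)`.
#' @export
buffer_pixel <- function(buf, x, y) {
  if (x < 0 || y < 0 || x >= buf$w || y >= buf$h)
    abort_invalid("pixel coordinates out of range")
  as.integer(buf$pixels[y + 1L, x + 1L, ])
}

#' @export
format.sc_pixel_buffer <- function(x, ...) {
  sprintf("<pixel buffer %dx%d>", x$w, x$h)
}

#' @export
print.sc_pixel_buffer <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Clip a rect to the buffer and return 1-based index ranges, or NULL when the
# intersection is empty.
clip_to_buffer <- function(buf, r) {
  x0 <- max(r$x, 0L); y0 <- max(r$y, 0L)
  x1 <- min(r$x + r$w, buf$w); y1 <- min(r$y + r$h, buf$h)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  list(rows = (y0 + 1L):y1, cols = (x0 + 1L):x1)
}

#' Fill a rectangular region with a solid color
#'
#' @param buf A pixel buffer (mutated in place).
#' @param r The region to fill (clipped to the buffer).
#' @param color Fill color.
#' @return The buffer, invisibly.
#' @export
buffer_fill_rect <- function(buf, r, color) {
  color <- parse_color(color)
  idx <- clip_to_buffer(buf, r)
  if (is.null(idx)) return(invisible(buf))
  for (ch in 1:3) buf$pixels[idx$rows, idx$cols, ch] <- color[ch]
  invisible(buf)
}

#' Draw a circle
#'
#' Draws the largest circle that fits in the square of the given diameter,
#' centered at `(cx, cy)` (continuous coordinates; the center of pixel
#' `(i, j)` is at `(i + 0.5, j + 0.5)`). Either filled or as a ring of the
#' given stroke width.
#'
#' @param buf A pixel buffer (mutated in place).
#' @param cx,cy Circle center in pixels.
#' @param radius Radius in pixels.
#' @param color Stroke/fill color.
#' @param filled Draw a disk (`TRUE`) or a ring (`FALSE`).
#' @param stroke Ring width in pixels when `filled = FALSE`.
#' @return The buffer, invisibly.
#' @export
buffer_draw_circle <- function(buf, cx, cy, radius, color,
                               filled = TRUE, stroke = 1) {
  color <- parse_color(color)
  if (radius <= 0) return(invisible(buf))
  x0 <- max(floor(cx - radius), 0); x1 <- min(ceiling(cx + radius), buf$w)
  y0 <- max(floor(cy - radius), 0); y1 <- min(ceiling(cy + radius), buf$h)
  if (x1 <= x0 || y1 <= y0) return(invisible(buf))
  xs <- (x0:(x1 - 1)) + 0.5
  ys <- (y0:(y1 - 1)) + 0.5
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  mask <- d2 <= radius^2
  if (!filled) mask <- mask & d2 > (max(radius - stroke, 0))^2
  hit <- which(mask, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(invisible(buf))
  rows <- (y0 + 1):y1; cols <- (x0 + 1):x1
  idx3 <- cbind(hit, rep(1L, nrow(hit)))
  for (ch in 1:3) {
    plane <- buf$pixels[rows, cols, ch, drop = FALSE]
    plane[idx3] <- color[ch]
    buf$pixels[rows, cols, ch] <- plane
  }
  invisible(buf)
}

# Nearest-neighbor index mapping from `n_out` target pixels onto `n_in`
# source pixels.
nn_index <- function(n_in, n_out) {
  pmin(floor(((seq_len(n_out) - 0.5) / n_out) * n_in) + 1L, n_in)
}

# Scale one channel plane to new dims. smooth = area-averaging box filter
# (each source pixel contributes to the target bin its center falls in);
# falls back to nearest-neighbor when upscaling along an axis.
scale_plane <- function(m, new_h, new_w, smooth) {
  sh <- nrow(m); sw <- ncol(m)
  if (sh == new_h && sw == new_w) return(m)
  if (!smooth || new_h > sh || new_w > sw) {
    return(m[nn_index(sh, new_h), nn_index(sw, new_w), drop = FALSE])
  }
  row_bin <- floor((seq_len(sh) - 1) * new_h / sh) + 1L
  col_bin <- floor((seq_len(sw) - 1) * new_w / sw) + 1L
  summed <- rowsum(m, row_bin)                     # new_h x sw
  summed <- t(rowsum(t(summed), col_bin))          # new_h x new_w
  counts <- tabulate(row_bin, new_h) %o% tabulate(col_bin, new_w)
  summed / counts
}

#' Blit an image into a region, scaling to fit the region exactly
#'
#' Copies an `h x w x 3` source array into the target region, resampling to
#' the region's size. Smooth scaling is an area-averaging box filter (the
#' appropriate choice for downscaling stimuli); nearest-neighbor is used when
#' `smooth = FALSE` or when upscaling.
#'
#' @param buf A pixel buffer (mutated in place).
#' @param src An `h x w x 3` numeric array with values 0-255.
#' @param r Target region.
#' @param smooth Use area-averaging (default) or nearest-neighbor.
#' @return The buffer, invisibly.
#' @export
buffer_blit <- function(buf, src, r, smooth = TRUE) {
  if (!is.array(src) || length(dim(src)) != 3L || dim(src)[3] != 3L)
    abort_invalid("blit source must be an h x w x 3 array")
  if (r$w <= 0L || r$h <= 0L) return(invisible(buf))
  scaled <- array(0L, dim = c(r$h, r$w, 3L))
  for (ch in 1:3) {
    plane <- scale_plane(src[, , ch, drop = TRUE], r$h, r$w, smooth)
    scaled[, , ch] <- as.integer(round_half_up(pmin(pmax(plane, 0), 255)))
  }
  idx <- clip_to_buffer(buf, r)
  if (is.null(idx)) return(invisible(buf))
  # offsets into the scaled image for the clipped part
  ro <- idx$rows - (r$y + 1L) + 1L
  co <- idx$cols - (r$x + 1L) + 1L
  buf$pixels[idx$rows, idx$cols, ] <- scaled[ro, co, , drop = FALSE]
  invisible(buf)
}

#' Content digest of a buffer
#'
#' A deterministic hash of the pixel contents, used by the headless display
#' backend's frame log and by regression tests.
#'
#' @param buf A pixel buffer.
#' @return A hex digest string.
#' @export
buffer_digest <- function(buf) {
  digest::digest(list(buf$w, buf$h, as.integer(buf$pixels)), algo = "md5")
}

#' Write a buffer to a PNG file
#'
#' @param buf A pixel buffer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_buffer_png <- function(buf, path) {
  arr <- buf$pixels / 255
  ok <- tryCatch({ png::writePNG(arr, target = path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write PNG to %s", path))
  invisible(path)
}

#' Read a PNG or BMP image as a pixel array
#'
#' Loads an image file into the `h x w x 3` integer array form accepted by
#' [image_element()] and [buffer_blit()]. Grayscale images are expanded to
#' RGB; an alpha channel, if present, is dropped (compositing is opaque).
#' BMP support covers the common uncompressed 24-bit format.
#'
#' @param path Path to a `.png` or `.bmp` file.
#' @return An `h x w x 3` integer array with values 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such image file: %s", path))
  magic <- readBin(path, "raw", n = 2L)
  if (identical(magic, as.raw(c(0x42, 0x4d)))) return(read_bmp24(path))
  arr <- tryCatch(png::readPNG(path), error = function(e)
    abort_io(sprintf("cannot read %s as PNG: %s", path, conditionMessage(e))))
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  array(as.integer(round_half_up(arr * 255)), dim = dim(arr))
}

# Minimal reader for uncompressed 24-bit BMP (BITMAPINFOHEADER, BI_RGB,
# bottom-up or top-down rows). No R package in the dependency set reads BMP.
read_bmp24 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 14L)
  offset <- readBin(hdr[11:14], "integer", size = 4L, endian = "little")
  info <- readBin(con, "raw", n = 40L)
  geti <- function(b, at) readBin(b[at:(at + 3L)], "integer",
                                  size = 4L, endian = "little")
  w <- geti(info, 5L)
  h <- geti(info, 9L)
  bpp <- readBin(info[15:16], "integer", size = 2L, endian = "little")
  compression <- geti(info, 17L)
  if (bpp != 24L || compression != 0L)
    abort_io(sprintf("%s: only uncompressed 24-bit BMP is supported", path))
  top_down <- h < 0
  h <- abs(h)
  seek(con, offset)
  row_bytes <- ((w * 3L + 3L) %/% 4L) * 4L       # rows padded to 4 bytes
  data <- readBin(con, "raw", n = row_bytes * h)
  if (length(data) < row_bytes * h) abort_io(sprintf("%s: truncated BMP", path))
  m <- matrix(as.integer(data), nrow = row_bytes)  # one column per stored row
  out <- array(0L, dim = c(h, w, 3L))
  cols <- seq_len(w)
  rows <- if (top_down) seq_len(h) else rev(seq_len(h))
  out[rows, , 1L] <- t(m[(cols - 1L) * 3L + 3L, , drop = FALSE]) # B G R order
  out[rows, , 2L] <- t(m[(cols - 1L) * 3L + 2L, , drop = FALSE])
  out[rows, , 3L] <- t(m[(cols - 1L) * 3L + 1L, , drop = FALSE])
  out
}
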