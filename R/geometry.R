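# Integer-pixel geometry: the deterministic arithmetic core that every layout
# calls. All rectangles are half-open: a rect covers pixel columns
# [x, x + w) and rows [y, y + h), origin at the top-left, y growing downward.

# round-half-up; base::round() rounds half to even, which would make segment
# boundaries depend on parity.
round_half_up <- function(x) floor(x + 0.5)

#' Integer pixel rectangle
#'
#' Creates a rectangle in screen coordinates: origin top-left, y axis pointing
#' down, half-open on the right and bottom edges (the rect covers pixel
#' columns `[x, x + w)` and rows `[y, y + h)`).
#'
#' @param x,y Integer pixel coordinates of the left and top edge.
#' @param w,h Non-negative integer width and height in pixels.
#' @return An object of class `"sc_rect"`.
#' @examples
#' rect(0, 0, 800, 600)
#' @export
rect <- function(x, y, w, h) {
  for (v in list(x, y, w, h)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != trunc(v))
      abort_invalid("rect coordinates must be single finite integers")
  }
  if (w < 0 || h < 0)
    abort_invalid("rect width and height must be >= 0")
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "sc_rect")
}

#' @export
format.sc_rect <- function(x, ...) {
  sprintf("<rect x=%d y=%d w=%d h=%d>", x$x, x$y, x$w, x$h)
}

#' @export
print.sc_rect <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

is_rect <- function(x) inherits(x, "sc_rect")

rect_right <- function(r) r$x + r$w
rect_bottom <- function(r) r$y + r$h

#' Test whether one rect is contained in another
#'
#' @param inner,outer Rects created by [rect()].
#' @return `TRUE` if every pixel of `inner` lies inside `outer`.
#' @export
rect_contains <- function(outer, inner) {
  inner$x >= outer$x && inner$y >= outer$y &&
    rect_right(inner) <= rect_right(outer) &&
    rect_bottom(inner) <= rect_bottom(outer)
}

#' Test whether a point lies inside a rect (half-open)
#'
#' The right and bottom edges are excluded: a click at `(x + w, y + h)` is
#' outside.
#'
#' @param r A rect.
#' @param px,py Pixel coordinates of the point.
#' @return `TRUE` or `FALSE`.
#' @export
rect_contains_point <- function(r, px, py) {
  px >= r$x && px < r$x + r$w && py >= r$y && py < r$y + r$h
}

#' Split an interval into proportional integer segments
#'
#' Divides `length` pixels among segments proportional to `weights`, using
#' cumulative-boundary rounding so that the segments always sum exactly to
#' `length`: boundary k is `round(length * sum(w[1:k]) / sum(w))` with round
#' half up, and segment i is the difference of consecutive boundaries.
#' Independent per-segment rounding could gain or lose pixels; the cumulative
#' rule cannot.
#'
#' @param length Total interval length in pixels (>= 0).
#' @param weights Non-negative weights, one per segment; at least one must be
#'   positive.
#' @return Integer vector of segment lengths summing to `length`.
#' @examples
#' split_interval(900, c(2, 1))   # 600 300
#' split_interval(100, c(1, 1, 1)) # 33 34 33
#' @export
split_interval <- function(length, weights) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
      length < 0 || length != trunc(length))
    abort_invalid("length must be a single non-negative integer")
  if (!is.numeric(weights) || length(weights) == 0L || anyNA(weights) ||
      any(weights < 0))
    abort_invalid("weights must be non-negative numbers")
  total <- sum(weights)
  if (total <= 0)
    abort_invalid("at least one weight must be positive")
  boundaries <- round_half_up(length * cumsum(weights) / total)
  as.integer(diff(c(0, boundaries)))
}

#' Inset a rect by per-side fractions
#'
#' Shrinks `outer` by removing a fraction of its width/height from each side
#' (the padding operation). The new origin moves by `round(left * w)` and
#' `round(top * h)`; the new extent is `round((1 - left - right) * w)` (and
#' analogously for height), with round half up. The result is always
#' contained in `outer`.
#'
#' @param outer A rect.
#' @param left,right,top,bottom Fractions in `[0, 1)`; `left + right < 1` and
#'   `top + bottom < 1`.
#' @return The inset rect.
#' @examples
#' inset_fractional(rect(0, 0, 1000, 500), 0.1, 0.1, 0.1, 0.1)
#' @export
inset_fractional <- function(outer, left = 0, right = 0, top = 0, bottom = 0) {
  if (!is_rect(outer)) abort_invalid("outer must be a rect")
  fr <- c(left, right, top, bottom)
  if (!is.numeric(fr) || anyNA(fr) || any(fr < 0) || any(fr >= 1))
    abort_invalid("padding fractions must lie in [0, 1)")
  if (left + right >= 1 || top + bottom >= 1)
    abort_invalid("opposing padding fractions must sum to less than 1")
  x <- outer$x + round_half_up(left * outer$w)
  y <- outer$y + round_half_up(top * outer$h)
  w <- round_half_up((1 - left - right) * outer$w)
  h <- round_half_up((1 - top - bottom) * outer$h)
  # cumulative rounding can overshoot by one pixel at extreme fractions;
  # clamp to preserve containment
  w <- min(w, outer$x + outer$w - x)
  h <- min(h, outer$y + outer$h - y)
  rect(x, y, w, h)
}

# Shared centering rule: offset of a segment of length `inner` centered in
# `outer_len`. Odd leftover pixels go to the right/bottom.
center_offset <- function(outer_len, inner) (outer_len - inner) %/% 2L

#' Fit content of a given size into a rect, preserving aspect ratio
#'
#' Computes the largest rectangle with the aspect ratio of
#' `content_w : content_h` that fits inside `outer`, centered (letterboxing).
#' The scale factor is `s = min(outer$w / content_w, outer$h / content_h)`;
#' with `allow_upscale = FALSE` it is additionally capped at 1, so content
#' smaller than the area is centered but never enlarged. Odd leftover space
#' goes to the right/bottom.
#'
#' @param content_w,content_h Positive content dimensions in pixels.
#' @param outer The available rect.
#' @param allow_upscale If `FALSE` (default), never scale above 1.
#' @return A rect contained in `outer`.
#' @examples
#' fit_rect(200, 100, rect(0, 0, 100, 100))               # (0, 25, 100, 50)
#' fit_rect(50, 50, rect(0, 0, 100, 100))                 # centered, no upscale
#' fit_rect(50, 50, rect(0, 0, 100, 100), allow_upscale = TRUE)
#' @export
fit_rect <- function(content_w, content_h, outer, allow_upscale = FALSE) {
  if (!is.numeric(content_w) || !is.numeric(content_h) ||
      length(content_w) != 1L || length(content_h) != 1L ||
      !is.finite(content_w) || !is.finite(content_h) ||
      content_w <= 0 || content_h <= 0)
    abort_invalid("content dimensions must be positive numbers")
  if (!is_rect(outer)) abort_invalid("outer must be a rect")
  if (outer$w == 0L || outer$h == 0L) return(rect(outer$x, outer$y, 0, 0))
  s <- min(outer$w / content_w, outer$h / content_h)
  if (!allow_upscale) s <- min(s, 1)
  w <- min(round_half_up(s * content_w), outer$w)
  h <- min(round_half_up(s * content_h), outer$h)
  rect(outer$x + center_offset(outer$w, w),
       outer$y + center_offset(outer$h, h),
       w, h)
}

#' Largest rect with given side proportions inside an area
#'
#' The biggest rectangle whose sides are in the ratio `prop_w : prop_h` that
#' fits in `outer`, centered. Identical to [fit_rect()] with upscaling
#' allowed, because proportions carry no native resolution.
#'
#' @param prop_w,prop_h Positive side proportions.
#' @param outer The available rect.
#' @return A rect contained in `outer`.
#' @examples
#' aspect_rect(1, 1, rect(0, 0, 200, 100)) # largest centered square
#' @export
aspect_rect <- function(prop_w, prop_h, outer) {
  if (!is.numeric(prop_w) || !is.numeric(prop_h) ||
      length(prop_w) != 1L || length(prop_h) != 1L ||
      !is.finite(prop_w) || !is.finite(prop_h) ||
      prop_w <= 0 || prop_h <= 0)
    abort_invalid("side proportions must be positive numbers")
  fit_rect(prop_w, prop_h, outer, allow_upscale = TRUE)
}
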