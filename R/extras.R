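# Render 2D numeric arrays as images: min-max normalize a scalar field, map
# it through a 256-entry palette, and hand the result to the composer as an
# image source. Typical uses: browsing slices of volumetric data, or stimuli
# generated from a mathematical formula.

#' Normalize a scalar field to [0, 1]
#'
#' Min-max normalization `v' = (v - min) / (max - min)`. A constant field
#' maps to all zeros (rather than dividing by zero).
#'
#' @param field A numeric matrix of finite values (rows x cols; row 1 is the
#'   top of the image).
#' @return A matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_field <- function(field) {
  if (!is.matrix(field) || !is.numeric(field) || length(field) == 0L)
    abort_invalid("field must be a non-empty numeric matrix")
  if (!all(is.finite(field)))
    abort_invalid("field values must all be finite")
  lo <- min(field); hi <- max(field)
  if (hi == lo) return(array(0, dim = dim(field)))
  (field - lo) / (hi - lo)
}

#' Built-in grayscale palette
#'
#' @return A 256 x 3 integer matrix; row k is the color for normalized value
#'   `(k - 1) / 255` (black to white).
#' @export
grayscale_palette <- function() {
  v <- 0:255
  cbind(r = v, g = v, b = v)
}

#' Convert a scalar field to an image
#'
#' Normalizes the field (see [normalize_field()]) and maps each value through
#' a 256-entry palette: value `v'` selects palette entry
#' `round(v' * 255) + 1`. The image has exactly one pixel per cell, with
#' field row 1 at the top, and is directly usable as an [image_element()]
#' source.
#'
#' @param field A numeric matrix of finite values.
#' @param palette A 256 x 3 matrix of RGB values 0-255 (default grayscale).
#' @return An `h x w x 3` integer array.
#' @examples
#' img <- field_to_image(matrix(c(0, 5, 10, 5), 2, 2))
#' @export
field_to_image <- function(field, palette = grayscale_palette()) {
  if (!is.matrix(palette) || nrow(palette) != 256L || ncol(palette) != 3L)
    abort_invalid("palette must be a 256 x 3 matrix")
  if (anyNA(palette) || any(palette < 0) || any(palette > 255))
    abort_invalid("palette entries must be RGB values in [0, 255]")
  norm <- normalize_field(field)
  idx <- as.integer(round_half_up(norm * 255)) + 1L
  out <- array(0L, dim = c(nrow(field), ncol(field), 3L))
  for (ch in 1:3)
    out[, , ch] <- matrix(as.integer(palette[idx, ch]), nrow(field), ncol(field))
  out
}

#' Read a scalar field from a whitespace-separated text file
#'
#' One row per line, values separated by whitespace — the plain-text matrix
#' interchange format used by the command-line renderer.
#'
#' @param path Path to the text file.
#' @return A numeric matrix.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such field file: %s", path))
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (!is.numeric(m)) abort_invalid(sprintf("%s does not contain a numeric matrix", path))
  m
}
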