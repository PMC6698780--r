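# RGB colors, parsed from "#RRGGBB" hex strings or (r, g, b) triples.

#' Parse a color specification
#'
#' Accepts either a hex string `"#RRGGBB"` (case-insensitive) or a numeric
#' triple of channel values in 0-255. Hex codes are the common way color
#' stimuli are specified in task scripts.
#'
#' @param spec A string like `"#FF0000"` or a length-3 numeric vector.
#' @return An integer vector `c(r, g, b)` of class `"sc_color"`.
#' @examples
#' parse_color("#FF0000")
#' parse_color(c(0, 128, 255))
#' @export
parse_color <- function(spec) {
  if (inherits(spec, "sc_color")) return(spec)
  if (is.character(spec) && length(spec) == 1L) {
    if (!grepl("^#[0-9a-fA-F]{6}$", spec))
      abort_color(sprintf("malformed hex color %s (expected \"#RRGGBB\")",
                          deparse(spec)))
    ch <- strtoi(substring(spec, c(2L, 4L, 6L), c(3L, 5L, 7L)), base = 16L)
    return(structure(as.integer(ch), class = "sc_color"))
  }
  if (is.numeric(spec) && length(spec) == 3L) {
    if (anyNA(spec) || any(spec < 0) || any(spec > 255) ||
        any(spec != trunc(spec)))
      abort_color("color channels must be integers in [0, 255]")
    return(structure(as.integer(spec), class = "sc_color"))
  }
  abort_color("color must be \"#RRGGBB\" or an (r, g, b) triple")
}

#' @export
format.sc_color <- function(x, ...) sprintf("#%02X%02X%02X", x[1], x[2], x[3])

#' @export
print.sc_color <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# A few named colors for convenience in examples and fixtures.
col_black <- function() parse_color(c(0L, 0L, 0L))
col_white <- function() parse_color(c(255L, 255L, 255L))
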