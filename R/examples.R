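# The three worked example screens. These are first-class fixtures: the test
# suite asserts their geometry from layout traces, and the CLI can render
# them to PNG.

offer_box <- function(amount, delay) {
  # a bordered box: the amount (bold) over the delay, amount given twice the
  # space (weights 2:1), both at font size 50
  border(lin_layout("v",
    ll_item(2, text_element(amount, font_size = 50, bold = TRUE)),
    ll_item(1, text_element(delay, font_size = 50))
  ))
}

symbol_primitive <- function(name, color = "#000000") {
  switch(name,
    circle = circle(color),
    cross = cross(color, stroke = 5),
    square = rectangle_shaper(1, 1, fill(color)),
    abort_invalid(sprintf("unknown symbol '%s' (use circle, cross, or square)",
                          name)))
}

stroop_train_stim <- function(mode, target_color, color_name) {
  if (mode == "color")
    padding_scale(0.5, rectangle_shaper(1.5, 1, fill(target_color)))
  else
    text_element(color_name, font_size = 50)
}

stroop_mapping_row <- function(mapping) {
  # one inner horizontal layout per color: two empty spacer slots on the
  # outsides, the key name and a colored square in the middle — giving one
  # empty slot at the screen edges but two between adjacent mappings
  entries <- lapply(seq_along(mapping$colors), function(i)
    lin_layout("h",
      NULL,
      text_element(mapping$keys[i], font_size = 40),
      rectangle_shaper(1, 1, fill(mapping$colors[i])),
      NULL))
  do.call(lin_layout, c(list("h"), entries))
}

#' Build one of the three example screens
#'
#' These fixtures cover the three canonical screen archetypes:
#'
#' * **Example 1** — an inter-temporal choice screen: the screen is split
#'   horizontally into two halves; each half is scaled down to 80% and filled
#'   with an offer box (a border around a vertical layout in which the bold
#'   amount text gets twice the space of the delay text, both font size 50).
#' * **Example 2** — a symbol-match screen: a vertical layout holding the
#'   instruction text, a horizontal row with the two symbols and three empty
#'   spacer slots between/around them, and one trailing empty slot that
#'   shifts everything upwards.
#' * **Example 3** — the training screen of a Stroop task: three vertically
#'   aligned rows of equal height — a caption, the training stimulus (a box
#'   in the target color, or the color's name as text), and the color-to-key
#'   mapping row built from per-color horizontal sublayouts with empty
#'   spacer slots on their outsides.
#'
#' @param id Example number: 1, 2, or 3.
#' @param amounts,delays Example 1: two strings each (left/right offer);
#'   defaults are an immediate 10 EUR vs 20 EUR after 30 days.
#' @param symbols Example 2: two of `"circle"`, `"cross"`, `"square"`.
#' @param instruction Example 2: instruction text.
#' @param mode Example 3: `"color"` (colored box) or `"text"` (color name).
#' @param target Example 3: target color (hex or triple).
#' @param target_name Example 3: the color's name for `mode = "text"`.
#' @param mapping Example 3: list with `colors` (character vector of hex
#'   colors) and `keys` (same-length character vector of key names).
#' @return The root element of the screen.
#' @examples
#' out <- compose_to_buffer(build_example(1), 1000, 1000)
#' trace_entries(out$trace, "border")
#' @export
build_example <- function(id,
                          amounts = c("10€", "20€"),
                          delays = c("now", "in 30 days"),
                          symbols = c("circle", "cross"),
                          instruction = "Are the symbols identical? (F = yes, J = no)",
                          mode = c("color", "text"),
                          target = "#00B400",
                          target_name = "green",
                          mapping = list(
                            colors = c("#C80000", "#00B400", "#0000C8", "#C8C800"),
                            keys = c("F", "G", "H", "J"))) {
  if (!is.numeric(id) || length(id) != 1L || !id %in% c(1, 2, 3))
    abort_invalid("example id must be 1, 2, or 3")
  if (id == 1) {
    if (length(amounts) != 2L || length(delays) != 2L)
      abort_invalid("example 1 needs two amounts and two delays")
    return(lin_layout("h",
      padding_scale(0.8, offer_box(amounts[1], delays[1])),
      padding_scale(0.8, offer_box(amounts[2], delays[2]))))
  }
  if (id == 2) {
    if (length(symbols) != 2L)
      abort_invalid("example 2 needs exactly two symbols")
    return(lin_layout("v",
      text_element(instruction),
      lin_layout("h",
        NULL,
        symbol_primitive(symbols[1]),
        NULL,
        symbol_primitive(symbols[2]),
        NULL),
      NULL))
  }
  mode <- match.arg(mode)
  if (length(mapping$colors) != length(mapping$keys) ||
      length(mapping$colors) == 0L)
    abort_invalid("mapping must pair each color with one key")
  lin_layout("v",
    text_element("target color:", font_size = 50),
    stroop_train_stim(mode, target, target_name),
    stroop_mapping_row(mapping))
}
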