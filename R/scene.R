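# The scene dialect: a JSON encoding of a render tree, one object per node —
# {"kind": "...", <attributes>, "children": [...]} — mapping 1:1 onto the
# element constructors, with colors as "#RRGGBB" strings. This is how the
# command-line renderer receives trees; programmatic use should construct
# elements directly.

#' Parse a scene JSON document into a render tree
#'
#' @param json A JSON string, or a path to a `.json` file.
#' @return The root element.
#' @section Dialect:
#' Node kinds and their attributes:
#' * `lin_layout`: `orientation`; `ll_item`: `relative_size`
#' * `grid_layout`: `rows` (array of arrays of nodes or `null`),
#'   `row_proportions`, `col_proportions`
#' * `overlay`; `padding`: `left`/`right`/`top`/`bottom` or `scale`
#' * `border`: `color`, `width`; `fill`: `color`
#' * `rectangle_shaper`: `prop_w`, `prop_h`
#' * `image`: `path` (PNG/BMP), `allow_upscale`, `smooth_scale`
#' * `field`: `path` (whitespace-separated numeric matrix, rendered in
#'   grayscale)
#' * `text`: `content`, `font_size`, `bold`, `color`, `align`
#' * `circle`: `color`, `filled`, `stroke`; `cross`: `color`, `stroke`
#' * `line`: `orientation`, `color`, `stroke`
#'
#' Wrappers take their single child as a one-element `children` array.
#' @export
scene_from_json <- function(json) {
  if (!is.character(json) || length(json) != 1L)
    abort_invalid("json must be a string or file path")
  src <- if (!grepl("^\\s*[{[]", json) && nchar(json) < 1000 &&
             file.exists(json)) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else json
  obj <- tryCatch(jsonlite::fromJSON(src, simplifyVector = FALSE),
                  error = function(e)
                    abort_invalid(sprintf("invalid scene JSON: %s",
                                          conditionMessage(e))))
  scene_node(obj, "/")
}

scene_children <- function(obj, path) {
  ch <- obj$children %||% list()
  lapply(seq_along(ch), function(i)
    if (is.null(ch[[i]])) NULL else scene_node(ch[[i]], child_path(path, i)))
}

scene_one_child <- function(obj, path) {
  ch <- scene_children(obj, path)
  if (length(ch) > 1L)
    abort_compose("wrapper node must have at most one child", path)
  if (length(ch) == 1L) ch[[1L]] else NULL
}

scene_node <- function(obj, path) {
  if (!is.list(obj) || is.null(obj$kind))
    abort_compose("scene node must be an object with a \"kind\" field", path)
  kind <- obj$kind
  tryCatch(switch(kind,
    lin_layout = do.call(lin_layout, c(list(obj$orientation %||% "horizontal"),
                                       scene_children(obj, path))),
    ll_item = ll_item(obj$relative_size %||% 1, scene_one_child(obj, path)),
    grid_layout = {
      rows <- lapply(seq_along(obj$rows), function(i)
        lapply(seq_along(obj$rows[[i]]), function(j) {
          cell <- obj$rows[[i]][[j]]
          if (is.null(cell)) NULL
          else scene_node(cell, paste0(child_path(path, i), ".", j))
        }))
      grid_layout(rows,
                  row_proportions = unlist(obj$row_proportions),
                  col_proportions = unlist(obj$col_proportions))
    },
    overlay = do.call(overlay, scene_children(obj, path)),
    padding = {
      child <- scene_one_child(obj, path)
      if (!is.null(obj$scale)) padding_scale(obj$scale, child)
      else padding(obj$left %||% 0, obj$right %||% 0,
                   obj$top %||% 0, obj$bottom %||% 0, child)
    },
    border = border(scene_one_child(obj, path),
                    color = obj$color %||% "#000000",
                    width = obj$width %||% 1),
    fill = fill(obj$color %||% "#000000", scene_one_child(obj, path)),
    rectangle_shaper = rectangle_shaper(obj$prop_w %||% 1, obj$prop_h %||% 1,
                                        scene_one_child(obj, path)),
    image = image_element(read_image(obj$path),
                          allow_upscale = isTRUE(obj$allow_upscale),
                          smooth_scale = !isFALSE(obj$smooth_scale)),
    field = image_element(field_to_image(read_field(obj$path))),
    text = text_element(obj$content %||% "",
                        font_size = obj$font_size %||% 32,
                        bold = isTRUE(obj$bold),
                        color = obj$color %||% "#000000",
                        align = obj$align %||% "center"),
    circle = circle(obj$color %||% "#000000",
                    filled = !isFALSE(obj$filled),
                    stroke = obj$stroke %||% 1),
    cross = cross(obj$color %||% "#000000", stroke = obj$stroke %||% 1),
    line = line_element(obj$orientation %||% "horizontal",
                        color = obj$color %||% "#000000",
                        stroke = obj$stroke %||% 1),
    abort_compose(sprintf("unknown scene node kind '%s'", kind), path)
  ),
  sc_composition_error = function(e) stop(e),
  sc_error = function(e)
    abort_compose(conditionMessage(e), path))
}
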