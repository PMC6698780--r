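# The render tree: normalization rules, the compose pass, trace invariants,
# and pixel-level behavior of wrappers and primitives.

test_that("normalize_child applies the auto-wrapping rules", {
  img <- gradient_image()
  wrapped <- normalize_child(img, context = "lin_layout")
  expect_identical(wrapped$kind, "ll_item")
  expect_identical(wrapped$children[[1]]$kind, "image")
  expect_false(wrapped$children[[1]]$allow_upscale)

  item <- ll_item(2, text_element("x"))
  expect_identical(normalize_child(item, "lin_layout"), item)

  plain <- text_element("x")
  expect_identical(normalize_child(plain, "lin_layout")$relative_size, 1)
  expect_null(normalize_child(NULL, "grid"))
  expect_identical(normalize_child(NULL, "lin_layout")$kind, "ll_item")
  # raw strings are NOT auto-wrapped; only images are
  expect_error(normalize_child("hello"), class = "sc_invalid_argument")
  expect_error(normalize_child(42), class = "sc_invalid_argument")
})

test_that("parse_color handles hex codes and triples", {
  expect_equal(as.integer(parse_color("#FF0000")), c(255L, 0L, 0L))
  expect_equal(as.integer(parse_color("#ffffff")), c(255L, 255L, 255L))
  expect_equal(as.integer(parse_color(c(0, 128, 255))), c(0L, 128L, 255L))
  expect_error(parse_color("#GG0000"), class = "sc_color_parse_error")
  expect_error(parse_color("#FFF"), class = "sc_color_parse_error")
  expect_error(parse_color(c(0, 300, 0)), class = "sc_color_parse_error")
})

test_that("a linear layout splits its area equally by default", {
  out <- compose_to_buffer(lin_layout("h", fill("#FF0000"), fill("#0000FF")),
                           100, 50)
  expect_equal(trace_rect(out$trace, "/1"), rect(0, 0, 50, 50))
  expect_equal(trace_rect(out$trace, "/2"), rect(50, 0, 50, 50))
  expect_equal(buffer_pixel(out$buffer, 0, 0), c(255L, 0L, 0L))
  expect_equal(buffer_pixel(out$buffer, 99, 49), c(0L, 0L, 255L))
})

test_that("a childless fill is the rectangle primitive", {
  out <- compose_to_buffer(fill("#FFFFFF"), 10, 10, background = "#000000")
  expect_length(out$trace$entries, 1)
  px <- buffer_pixels(out$buffer)
  expect_true(all(px == 255L))
})

test_that("compose of NULL draws nothing and yields an empty trace", {
  out <- compose_to_buffer(NULL, 10, 10, background = "#123456")
  expect_length(out$trace$entries, 0)
  expect_equal(buffer_pixel(out$buffer, 5, 5), c(0x12, 0x34, 0x56))
})

test_that("overlay draws later children over earlier ones", {
  out <- compose_to_buffer(overlay(fill("#FF0000"), fill("#0000FF")), 20, 20)
  expect_true(all(buffer_pixels(out$buffer)[, , 3] == 255L))
  expect_true(all(buffer_pixels(out$buffer)[, , 1] == 0L))
})

test_that("grid row heights depend only on proportions, never on content", {
  big_text <- text_element(strrep("x", 500), font_size = 90)
  g1 <- grid_layout(list(list(big_text, NULL), list(fill("#FF0000"), NULL)),
                    row_proportions = c(3, 1))
  g2 <- grid_layout(list(list(fill("#00FF00"), NULL), list(NULL, circle())),
                    row_proportions = c(3, 1))
  t1 <- compose_to_buffer(g1, 200, 100)$trace
  t2 <- compose_to_buffer(g2, 200, 100)$trace
  expect_equal(trace_rect(t1, "/1.1")$h, 75)
  expect_equal(trace_rect(t2, "/1.1")$h, 75)
  expect_equal(trace_rect(t1, "/2.1")$y, 75)
})

test_that("ragged grid rows are padded with empty cells on the right", {
  g <- grid_layout(list(list(fill("#FF0000")),
                        list(fill("#00FF00"), fill("#0000FF"))))
  tr <- compose_to_buffer(g, 100, 100)$trace
  kinds <- vapply(tr$entries, `[[`, "", "kind")
  expect_equal(sum(kinds == "fill"), 3)
  expect_equal(trace_rect(tr, "/1.1"), rect(0, 0, 50, 50))
  expect_equal(trace_rect(tr, "/2.2"), rect(50, 50, 50, 50))
})

test_that("border draws its stroke inside and insets the child", {
  out <- compose_to_buffer(border(fill("#FFFFFF"), "#FF0000", width = 2),
                           50, 50, background = "#000000")
  # hand-derived: child area inset by the stroke width on each side
  expect_equal(trace_rect(out$trace, "/1"), rect(2, 2, 46, 46))
  expect_equal(buffer_pixel(out$buffer, 0, 0), c(255L, 0L, 0L))
  expect_equal(buffer_pixel(out$buffer, 1, 25), c(255L, 0L, 0L))
  expect_equal(buffer_pixel(out$buffer, 2, 25), c(255L, 255L, 255L))
  expect_equal(buffer_pixel(out$buffer, 49, 49), c(255L, 0L, 0L))
})

test_that("wrappers with no child only shape/draw; nothing else happens", {
  out <- compose_to_buffer(padding(0.2, 0.2, 0.2, 0.2), 50, 50,
                           background = "#112233")
  expect_true(all(buffer_pixels(out$buffer)[, , 1] == 0x11))
  out2 <- compose_to_buffer(border(width = 1), 10, 10, background = "#FFFFFF")
  expect_equal(buffer_pixel(out2$buffer, 0, 0), c(0L, 0L, 0L))
  expect_equal(buffer_pixel(out2$buffer, 5, 5), c(255L, 255L, 255L))
})

test_that("primitives center in their area per the shared centering rule", {
  # line: stroke 1 in a 20-px-tall area -> row floor((20 - 1)/2) = 9
  out <- compose_to_buffer(line_element("h", "#FF0000"), 100, 20,
                           background = "#FFFFFF")
  px <- buffer_pixels(out$buffer)
  expect_true(all(px[10, , 1] == 255L & px[10, , 2] == 0L))  # row y=9 (1-based 10)
  expect_true(all(px[9, , 2] == 255L))   # rows above/below untouched
  expect_true(all(px[11, , 2] == 255L))

  # cross spans the full width and height
  out2 <- compose_to_buffer(cross("#000000", stroke = 2), 21, 11,
                            background = "#FFFFFF")
  px2 <- buffer_pixels(out2$buffer)
  expect_true(all(px2[5:6, , 1] == 0L))       # horizontal bar rows y=4,5
  expect_true(all(px2[, 10:11, 1] == 0L))     # vertical bar cols x=9,10
  expect_equal(px2[1, 1, 1], 255L)

  # circle: largest centered disk, diameter min(w, h)
  out3 <- compose_to_buffer(circle("#000000"), 100, 60, background = "#FFFFFF")
  px3 <- buffer_pixels(out3$buffer)
  expect_equal(px3[30, 50, 1], 0L)            # center is inked
  expect_equal(px3[30, 19, 1], 255L)          # left of the disk (x < 20)
  expect_equal(px3[30, 22, 1], 0L)            # just inside the disk
  expect_equal(px3[1, 50, 1], 0L)             # disk spans the full height
  expect_equal(px3[1, 5, 1], 255L)            # corner stays background
})

test_that("images scale down to fit, center, and never upscale by default", {
  img <- gradient_image(10, 20)  # 20x10 image
  out <- compose_to_buffer(image_element(img), 10, 10)
  # fit 20x10 into 10x10 -> 10x5 centered
  entry <- trace_entries(out$trace, "image")[[1]]
  expect_equal(entry$rect, rect(0, 0, 10, 10))  # node gets the full area
  # small image in a big area: centered, not upscaled
  small <- gradient_image(4, 4)
  out2 <- compose_to_buffer(image_element(small), 100, 100,
                            background = "#FFFFFF")
  px <- buffer_pixels(out2$buffer)
  inked <- which(px[, , 3] == 128L, arr.ind = TRUE)
  expect_equal(nrow(inked), 16)  # exactly 4x4 pixels at native size
  expect_equal(range(inked[, 1]), c(49, 52))  # centered: rows 48..51 0-based
  expect_equal(range(inked[, 2]), c(49, 52))
})

test_that("text renders clipped, aligned, and vertically centered", {
  # font 32: advance 20, line height 38, glyph height 32
  t <- text_element("ab", font_size = 32, color = "#FF0000", align = "left")
  out <- compose_to_buffer(t, 200, 100, background = "#FFFFFF")
  px <- buffer_pixels(out$buffer)
  ink <- which(px[, , 2] == 0L, arr.ind = TRUE)
  # leftmost ink at area.x; block top = (100 - 38) %/% 2 + (38 - 32) %/% 2 = 34
  expect_equal(min(ink[, 2]), 1)
  expect_equal(min(ink[, 1]), 35)  # 0-based y = 34
  expect_equal(max(ink[, 1]), 35 + 32 - 1)
  # two glyphs of ink width 19 separated by a 1-px gap at advance boundary
  expect_equal(max(ink[, 2]), 39)  # second glyph ends at x = 20 + 19 = col 39

  # two-line content: block of 2 lines centered
  t2 <- text_element("a\nb", font_size = 32, color = "#FF0000")
  out2 <- compose_to_buffer(t2, 100, 100, background = "#FFFFFF")
  ink2 <- which(buffer_pixels(out2$buffer)[, , 2] == 0L, arr.ind = TRUE)
  # block height 76, top = 12; line 1 glyph top = 12 + 3 = 15 (0-based);
  # line 2 glyph spans 53..84 0-based
  expect_equal(min(ink2[, 1]), 16)
  expect_equal(max(ink2[, 1]), 85)
  # empty text draws nothing
  out3 <- compose_to_buffer(text_element(""), 50, 50, background = "#FFFFFF")
  expect_true(all(buffer_pixels(out3$buffer) == 255L))
})

test_that("composition errors name the offending node path", {
  bad <- fill("#FFFFFF", text_element("x"))
  bad$children <- c(bad$children, list(text_element("y")))  # corrupt wrapper
  err <- tryCatch(compose_to_buffer(lin_layout("h", bad), 10, 10),
                  sc_composition_error = function(e) e)
  expect_s3_class(err, "sc_composition_error")
  expect_match(conditionMessage(err), "/1/1")
})

test_that("randomized trees: tiling, containment, proportionality", {
  set.seed(101)
  for (i in 1:60) {
    tree <- random_tree(3)
    if (is.null(tree)) next
    w <- sample(40:300, 1); h <- sample(40:300, 1)
    tr <- compose_to_buffer(tree, w, h)$trace
    expect_true(trace_containment_ok(tr))
    # check every lin_layout's slots tile its axis exactly
    df <- as.data.frame(tr)
    for (k in which(df$kind == "lin_layout")) {
      parent <- df[k, ]
      slots <- df[df$kind == "ll_item" &
                  dirname2(df$path) == parent$path, , drop = FALSE]
      if (nrow(slots) == 0) next
      horizontal <- all(slots$h == parent$h)
      if (horizontal && nrow(slots) > 0) {
        expect_equal(sum(slots$w), parent$w)
        expect_equal(min(slots$x), parent$x)
      } else {
        expect_equal(sum(slots$h), parent$h)
        expect_equal(min(slots$y), parent$y)
      }
    }
  }
})

test_that("ll_item slot lengths match relative sizes within 1 px", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(2:5, 1)
    weights <- sample(c(0.5, 1, 2, 3), n, replace = TRUE)
    items <- lapply(weights, function(w) ll_item(w, fill("#808080")))
    tree <- do.call(lin_layout, c(list("h"), items))
    len <- sample(50:1000, 1)
    tr <- compose_to_buffer(tree, len, 10)$trace
    widths <- vapply(seq_len(n),
                     function(k) trace_rect(tr, sprintf("/%d", k))$w, 0L)
    exact <- len * weights / sum(weights)
    expect_true(all(abs(widths - exact) <= 1))
  }
})

test_that("compose is deterministic: identical pixels and trace across runs", {
  set.seed(77)
  for (i in 1:20) {
    tree <- random_tree(3)
    if (is.null(tree)) next
    a <- compose_to_buffer(tree, 120, 90)
    b <- compose_to_buffer(tree, 120, 90)
    expect_identical(buffer_pixels(a$buffer), buffer_pixels(b$buffer))
    expect_identical(as.data.frame(a$trace), as.data.frame(b$trace))
  }
})

test_that("no-upscale: image draw rect never exceeds source dims", {
  set.seed(88)
  for (i in 1:50) {
    ih <- sample(1:60, 1); iw <- sample(1:60, 1)
    img <- array(100L, dim = c(ih, iw, 3))
    aw <- sample(1:200, 1); ah <- sample(1:200, 1)
    dest <- fit_rect(iw, ih, rect(0, 0, aw, ah), allow_upscale = FALSE)
    expect_lte(dest$w, iw)
    expect_lte(dest$h, ih)
    expect_true(rect_contains(rect(0, 0, aw, ah), dest))
  }
})
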