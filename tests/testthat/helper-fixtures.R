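# Shared fixtures: a guarded display context and a random render-tree
# generator for property-style tests.

# Ensure a fresh headless display for a test; torn down afterwards.
local_display <- function(resolution = c(80, 60), keep_frames = FALSE,
                          env = parent.frame()) {
  display_quit()
  ctx <- display_init(resolution, backend = "headless",
                      keep_frames = keep_frames)
  withr::defer(display_quit(), envir = env)
  ctx
}

random_color <- function() {
  parse_color(sample(0:255, 3, replace = TRUE))
}

# Random tree of layouts/wrappers/primitives. depth limits nesting; the
# caller sets the seed.
random_tree <- function(depth = 3) {
  leaf <- function() {
    switch(sample(c("fill", "circle", "cross", "line", "text", "spacer"), 1),
      fill = fill(random_color()),
      circle = circle(random_color(), filled = sample(c(TRUE, FALSE), 1),
                      stroke = sample(1:4, 1)),
      cross = cross(random_color(), stroke = sample(1:4, 1)),
      line = line_element(sample(c("h", "v"), 1), random_color(),
                          stroke = sample(1:3, 1)),
      text = text_element(paste(sample(letters, sample(1:8, 1),
                                       replace = TRUE), collapse = ""),
                          font_size = sample(8:40, 1),
                          align = sample(c("left", "center", "right"), 1)),
      spacer = NULL)
  }
  if (depth <= 0) return(leaf())
  kind <- sample(c("lin", "overlay", "padding", "border", "fill",
                   "shaper", "grid", "leaf"), 1,
                 prob = c(3, 1, 1, 1, 1, 1, 1, 3))
  switch(kind,
    lin = {
      n <- sample(1:4, 1)
      children <- lapply(seq_len(n), function(i) {
        w <- sample(c(1, 1, 2, 3, 0.5), 1)
        ll_item(w, random_tree(depth - 1))
      })
      do.call(lin_layout, c(list(sample(c("h", "v"), 1)), children))
    },
    overlay = do.call(overlay, lapply(seq_len(sample(1:3, 1)), function(i) {
      x <- random_tree(depth - 1)
      if (is.null(x)) fill(random_color()) else x
    })),
    padding = padding(runif(1, 0, 0.3), runif(1, 0, 0.3),
                      runif(1, 0, 0.3), runif(1, 0, 0.3),
                      random_tree(depth - 1)),
    border = border(random_tree(depth - 1), random_color(),
                    width = sample(1:3, 1)),
    fill = fill(random_color(), random_tree(depth - 1)),
    shaper = rectangle_shaper(runif(1, 0.3, 3), runif(1, 0.3, 3),
                              random_tree(depth - 1)),
    grid = {
      nr <- sample(1:3, 1); nc <- sample(1:3, 1)
      rows <- lapply(seq_len(nr), function(i)
        lapply(seq_len(nc), function(j)
          if (runif(1) < 0.25) NULL else random_tree(depth - 1)))
      grid_layout(rows)
    },
    leaf = leaf())
}

# Parent path of a trace node path ("/a/b" -> "/a", "/a" -> "/").
dirname2 <- function(p) {
  vapply(p, function(x) {
    if (x == "/") return(NA_character_)
    d <- sub("/[^/]+$", "", x)
    if (d == "") "/" else d
  }, "", USE.NAMES = FALSE)
}

# A deterministic small test image: 4x6 RGB gradient.
gradient_image <- function(h = 4, w = 6) {
  arr <- array(0L, dim = c(h, w, 3))
  arr[, , 1] <- matrix(rep(seq(0, 255, length.out = w), each = h), h, w)
  arr[, , 2] <- matrix(rep(seq(255, 0, length.out = h), times = w), h, w)
  arr[, , 3] <- 128L
  array(as.integer(round(arr)), dim = dim(arr))
}
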