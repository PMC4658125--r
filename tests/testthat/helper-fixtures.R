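# small in-code image builders shared across tests

# uniform grey RGB image
grey_image <- function(h, w, shade = 128L) {
  source_image(array(as.integer(shade), dim = c(h, w, 3L)))
}

# white image with a dark axis-aligned square block (1-based row/col ranges)
square_image <- function(h, w, rows, cols, shade = 0L, bg = 255L) {
  m <- matrix(as.integer(bg), h, w)
  m[rows, cols] <- as.integer(shade)
  source_image(m)
}

# RGB test pattern whose channels encode (row, col) so any pixel can be
# traced through a geometric transform
numbered_pattern <- function(h, w) {
  r <- matrix(seq_len(h) %% 256L, h, w)
  c_ <- matrix(rep(seq_len(w) %% 256L, each = h), h, w)
  source_image(array(as.integer(c(r, c_, (r + c_) %% 256L)), dim = c(h, w, 3L)))
}

edge_map_of <- function(mask) {
  structure(list(mask = mask, magnitude = NULL,
                 width = ncol(mask), height = nrow(mask)),
            class = "edge_map")
}

random_boxes <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    x0 <- runif(n, 0, 0.8); y0 <- runif(n, 0, 0.8)
    as_boxes(tibble::tibble(
      x0 = x0, y0 = y0,
      x1 = x0 + runif(n, 0.05, 0.2), y1 = y0 + runif(n, 0.05, 0.2),
      rotation = sample(c(0L, 90L, 180L, 270L), n, replace = TRUE),
      fields = lapply(seq_len(n), function(i) {
        if (i %% 2L == 0L) c(catalogNumber = sprintf("%09d", i), locality = "here")
        else stats::setNames(character(), character())
      })))
  })
}

# a tiny scan + document on disk; returns the document
make_test_scan <- function(dir, name = "scan1.png", h = 60L, w = 90L) {
  path <- file.path(dir, name)
  img <- numbered_pattern(h, w)
  write_image(img, path)
  path
}

hymenoptera_template <- function() {
  read_template(system.file("extdata", "templates", "hymenoptera.inselect_template",
                            package = "drawerseg", mustWork = TRUE))
}
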