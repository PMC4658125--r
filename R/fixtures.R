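#' Synthetic drawer specification
#'
#' Describes a synthetic whole-drawer scan: dark elongated specimen bodies
#' (ellipse plus a thin pin line) with a small bordered white label beneath,
#' on a light drawer-bottom background, optionally grouped into unit-tray
#' outlines, with an optional low-contrast rhombus-tiling distractor pattern
#' in the empty regions (emulating printed tiling paper present in real
#' drawer scans). Fully determined by `seed`.
#'
#' Defaults describe a thumbnail-scale drawer: 1600 x 1200 px, 12 specimens
#' of 60--120 px, background shade 200 with pixel noise sd 2 — enough edge
#' structure for the gradient pipeline without modelling real insects.
#'
#' @param width,height Canvas size in pixels.
#' @param n_specimens Number of specimens to place.
#' @param size_range Specimen body width range in pixels.
#' @param tray_layout Optional `c(rows, cols)` of unit-tray outlines.
#' @param distractor Draw the low-contrast tiling pattern?
#' @param background Background shade (8-bit).
#' @param noise_sd Gaussian pixel noise sd (8-bit units).
#' @param spacing Minimum gap between specimen extents in pixels.
#' @param seed RNG seed; identical specs give byte-identical images.
#' @return A `drawer_spec` object.
#' @export
drawer_spec <- function(width = 1600L, height = 1200L, n_specimens = 12L,
                        size_range = c(60L, 120L), tray_layout = NULL,
                        distractor = FALSE, background = 200L, noise_sd = 2,
                        spacing = 20L, seed = 0L) {
  stopifnot(width >= 64, height >= 64, n_specimens >= 0,
            length(size_range) == 2L, size_range[1] <= size_range[2])
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_specimens = as.integer(n_specimens),
                 size_range = as.integer(size_range),
                 tray_layout = if (is.null(tray_layout)) NULL else as.integer(tray_layout),
                 distractor = isTRUE(distractor),
                 background = as.integer(background), noise_sd = noise_sd,
                 spacing = as.integer(spacing), seed = as.integer(seed)),
            class = "drawer_spec")
}

fill_rect <- function(canvas, x0, y0, x1, y1, shade) {
  canvas[clamp((y0 + 1L):y1, 1L, nrow(canvas)), clamp((x0 + 1L):x1, 1L, ncol(canvas))] <- shade
  canvas
}

outline_rect <- function(canvas, x0, y0, x1, y1, shade, thickness = 2L) {
  canvas <- fill_rect(canvas, x0, y0, x1, y0 + thickness, shade)
  canvas <- fill_rect(canvas, x0, y1 - thickness, x1, y1, shade)
  canvas <- fill_rect(canvas, x0, y0, x0 + thickness, y1, shade)
  fill_rect(canvas, x1 - thickness, y0, x1, y1, shade)
}

fill_ellipse <- function(canvas, cx, cy, a, b, shade) {
  ys <- clamp(floor(cy - b):ceiling(cy + b), 1L, nrow(canvas))
  xs <- clamp(floor(cx - a):ceiling(cx + a), 1L, ncol(canvas))
  sub <- outer(((ys - cy) / b)^2, ((xs - cx) / a)^2, `+`) <= 1
  block <- canvas[ys, xs]
  block[sub] <- shade
  canvas[ys, xs] <- block
  canvas
}

# one specimen: pin tip above, ellipse body, bordered white label beneath
# (overlapping the body so edge contours stay connected); returns the canvas
# and the drawn extent (0-based half-open pixel rect)
draw_specimen <- function(canvas, x0, y0, body_w, body_h, label_w, label_h,
                          body_shade) {
  pin <- 8L
  cx <- x0 + body_w / 2
  cy <- y0 + pin + body_h / 2
  canvas <- fill_rect(canvas, as.integer(round(cx)) - 1L, y0,
                      as.integer(round(cx)) + 1L, as.integer(round(cy)), 60L)
  canvas <- fill_ellipse(canvas, cx + 0.5, cy + 0.5, body_w / 2, body_h / 2, body_shade)
  lx0 <- as.integer(round(cx - label_w / 2)); lx1 <- lx0 + label_w
  ly0 <- y0 + pin + body_h - 2L; ly1 <- ly0 + label_h
  canvas <- fill_rect(canvas, lx0, ly0, lx1, ly1, 255L)
  canvas <- outline_rect(canvas, lx0, ly0, lx1, ly1, 80L, thickness = 1L)
  ext <- c(x0 = min(x0, lx0), y0 = y0, x1 = max(x0 + body_w, lx1), y1 = ly1)
  list(canvas = canvas, extent = ext)
}

draw_tiling <- function(canvas, shade, pitch = 40L) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  idx <- outer(seq_len(nr), seq_len(nc), `+`)
  idx2 <- outer(seq_len(nr), rev(seq_len(nc)), `+`)
  canvas[idx %% pitch == 0L | idx2 %% pitch == 0L] <- shade
  canvas
}

#' Generate a synthetic drawer scan with ground truth
#'
#' @param spec A [drawer_spec()].
#' @return A list with `image` (a [source_image]) and `truth` (tibble of
#'   normalized specimen extents: `label, x0, y0, x1, y1`).
#' @export
generate_drawer <- function(spec) {
  stopifnot(inherits(spec, "drawer_spec"))
  withr::with_seed(spec$seed, generate_drawer_impl(spec))
}

generate_drawer_impl <- function(spec) {
  w <- spec$width; h <- spec$height
  canvas <- matrix(spec$background, h, w)
  if (spec$distractor) canvas <- draw_tiling(canvas, spec$background + 6L)
  regions <- list(c(x0 = 20L, y0 = 20L, x1 = w - 20L, y1 = h - 20L))
  if (!is.null(spec$tray_layout)) {
    tr <- spec$tray_layout[1]; tc <- spec$tray_layout[2]
    cw <- (w - 24L) %/% tc; ch <- (h - 24L) %/% tr
    regions <- list()
    for (r in seq_len(tr)) for (c in seq_len(tc)) {
      x0 <- 12L + (c - 1L) * cw + 4L; y0 <- 12L + (r - 1L) * ch + 4L
      x1 <- 12L + c * cw - 4L; y1 <- 12L + r * ch - 4L
      # a unit tray reads as a white card interior with a dark rim shadow
      canvas <- fill_rect(canvas, x0, y0, x1, y1, 255L)
      canvas <- outline_rect(canvas, x0, y0, x1, y1, 60L, thickness = 1L)
      regions[[length(regions) + 1L]] <- c(x0 = x0 + 14L, y0 = y0 + 14L,
                                           x1 = x1 - 14L, y1 = y1 - 14L)
    }
  }
  placed <- list()
  truth <- vector("list", spec$n_specimens)
  for (i in seq_len(spec$n_specimens)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      body_w <- as.integer(sample(spec$size_range[1]:spec$size_range[2], 1L))
      body_h <- as.integer(round(body_w * stats::runif(1, 0.45, 0.7)))
      label_w <- max(18L, as.integer(round(0.5 * body_w)))
      label_h <- 12L
      ext_w <- max(body_w, label_w); ext_h <- 8L + body_h + label_h - 2L
      reg <- regions[[((i - 1L) %% length(regions)) + 1L]]
      if (reg["x1"] - reg["x0"] < ext_w || reg["y1"] - reg["y0"] < ext_h) next
      px <- as.integer(sample(reg["x0"]:(reg["x1"] - ext_w), 1L))
      py <- as.integer(sample(reg["y0"]:(reg["y1"] - ext_h), 1L))
      cand <- c(px, py, px + ext_w, py + ext_h)
      clash <- any(map_lgl(placed, function(q) {
        cand[1] < q[3] + spec$spacing && q[1] < cand[3] + spec$spacing &&
          cand[2] < q[4] + spec$spacing && q[2] < cand[4] + spec$spacing
      }))
      if (clash) next
      shade <- as.integer(sample(30:55, 1L))
      drawn <- draw_specimen(canvas, px + as.integer((ext_w - body_w) / 2), py,
                             body_w, body_h, label_w, label_h, shade)
      canvas <- drawn$canvas
      placed[[length(placed) + 1L]] <- cand
      e <- drawn$extent
      truth[[i]] <- tibble(label = sprintf("specimen-%02d", i),
                           x0 = round_coord(e[["x0"]] / w), y0 = round_coord(e[["y0"]] / h),
                           x1 = round_coord(e[["x1"]] / w), y1 = round_coord(e[["y1"]] / h))
      ok <- TRUE
      break
    }
    if (!ok)
      abort(sprintf("could not place specimen %d after 200 attempts; canvas too small", i),
            class = "drawerseg_spec_error")
  }
  if (spec$noise_sd > 0)
    canvas <- canvas + matrix(round(stats::rnorm(h * w, 0, spec$noise_sd)), h, w)
  canvas <- clamp(canvas, 0L, 255L)
  storage.mode(canvas) <- "integer"
  list(image = source_image(canvas),
       truth = if (spec$n_specimens) bind_rows(truth)
               else tibble(label = character(), x0 = double(), y0 = double(),
                           x1 = double(), y1 = double()))
}

#' Generate a synthetic slide-grid scan with ground truth
#'
#' Standard microscope slides laid out for imaging in a rectangular grid —
#' six columns by twelve rows for standard slides (72 sockets), six by eight
#' for large slides. Each occupied socket carries a dark slide outline with a
#' frosted label band at one end (touching the outline) and a faint coverslip
#' region. Occupied sockets are a seeded sample of
#' `floor(occupancy * cols * rows)` positions; ground truth is the occupied
#' slide extents.
#'
#' @param cols,rows Grid dimensions.
#' @param occupancy Fraction of sockets occupied, in `[0, 1]`.
#' @param seed RNG seed for the socket sample.
#' @return A list with `image` (a [source_image]) and `truth` (tibble of
#'   normalized slide extents).
#' @export
generate_slide_grid <- function(cols = 6L, rows = 12L, occupancy = 1, seed = 0L) {
  stopifnot(cols >= 1, rows >= 1, occupancy >= 0, occupancy <= 1)
  withr::with_seed(as.integer(seed), {
    slide_w <- 150L; slide_h <- 50L; gap_x <- 30L; gap_y <- 18L; margin <- 24L
    w <- 2L * margin + cols * slide_w + (cols - 1L) * gap_x
    h <- 2L * margin + rows * slide_h + (rows - 1L) * gap_y
    canvas <- matrix(235L, h, w)
    n <- as.integer(cols * rows)
    n_occ <- as.integer(floor(occupancy * n))
    occ <- sort(sample.int(n, n_occ))
    truth <- vector("list", n_occ)
    for (k in seq_along(occ)) {
      idx <- occ[k] - 1L
      r <- idx %/% cols; c <- idx %% cols
      x0 <- margin + c * (slide_w + gap_x); y0 <- margin + r * (slide_h + gap_y)
      x1 <- x0 + slide_w; y1 <- y0 + slide_h
      # slide glass reads as one filled region in a scan; the frosted label
      # band spans the full height so its edges join the slide boundary, and
      # the coverslip contrast is faint (below the default edge threshold)
      canvas <- fill_rect(canvas, x0, y0, x1, y1, 120L)
      canvas <- fill_rect(canvas, x0, y0, x0 + 36L, y1, 250L)
      canvas <- fill_rect(canvas, x0 + 70L, y0 + 8L, x0 + 120L, y1 - 8L, 128L)
      truth[[k]] <- tibble(label = sprintf("slide-%03d", occ[k]),
                           x0 = round_coord(x0 / w), y0 = round_coord(y0 / h),
                           x1 = round_coord(x1 / w), y1 = round_coord(y1 / h))
    }
    canvas <- clamp(canvas + matrix(round(stats::rnorm(h * w, 0, 1.5)), h, w), 0L, 255L)
    storage.mode(canvas) <- "integer"
    list(image = source_image(canvas),
         truth = if (n_occ) bind_rows(truth)
                 else tibble(label = character(), x0 = double(), y0 = double(),
                             x1 = double(), y1 = double()))
  })
}

#' Write a fixture to disk (image plus ground-truth CSV)
#'
#' @param fixture A list with `image` and `truth` as returned by the
#'   generators.
#' @param path Output image path (`.png` or `.tif`); the truth table is
#'   written beside it as `<stem>_truth.csv` using the metadata-export
#'   column convention.
#' @return The image path, invisibly.
#' @export
write_fixture <- function(fixture, path) {
  write_image(fixture$image, path)
  stem <- tools::file_path_sans_ext(basename(path))
  truth <- fixture$truth
  out <- tibble(file = stem, box = seq_len(nrow(truth)),
                x0 = truth$x0, y0 = truth$y0, x1 = truth$x1, y1 = truth$y1,
                rotation = 0L, label = truth$label)
  readr::write_csv(out, file.path(dirname(path), paste0(stem, "_truth.csv")))
  invisible(path)
}
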