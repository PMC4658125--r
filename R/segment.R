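#' Segmentation parameters
#'
#' The automatic segmenter's free parameters. The operator sequence (CIELAB
#' conversion, Gaussian blur, Sobel gradients, threshold, recursive contour
#' extraction) is fixed; these values tune it and are pinned here so runs are
#' reproducible.
#'
#' @param blur_kernel Odd Gaussian kernel width in pixels (default 5).
#' @param blur_sigma Gaussian sigma in pixels; 0 (the default) derives sigma
#'   from the kernel width as `0.3 * ((k - 1) / 2 - 1) + 0.8`.
#' @param edge_threshold Gradient-magnitude threshold on the 0--255 scale
#'   (default 40).
#' @param min_box_fraction Boxes smaller than this fraction of the image area
#'   are discarded as noise (default 1e-5).
#' @param max_box_fraction Boxes larger than this fraction are treated as
#'   containers (unit trays) and re-segmented inside (default 0.5).
#' @param max_depth Maximum recursion depth for edges-within-edges
#'   (default 2: drawer then tray).
#' @return A `seg_params` object.
#' @export
seg_params <- function(blur_kernel = 5L, blur_sigma = 0, edge_threshold = 40,
                       min_box_fraction = 1e-5, max_box_fraction = 0.5,
                       max_depth = 2L) {
  if (!is_count(blur_kernel) || blur_kernel %% 2L == 0L)
    stop_param("`blur_kernel` must be an odd positive integer")
  if (blur_sigma < 0) stop_param("`blur_sigma` must be >= 0")
  if (!(min_box_fraction >= 0 && min_box_fraction < max_box_fraction && max_box_fraction <= 1))
    stop_param("need 0 <= min_box_fraction < max_box_fraction <= 1")
  if (!is_count(max_depth)) stop_param("`max_depth` must be >= 1")
  structure(list(blur_kernel = as.integer(blur_kernel), blur_sigma = blur_sigma,
                 edge_threshold = edge_threshold,
                 min_box_fraction = min_box_fraction,
                 max_box_fraction = max_box_fraction,
                 max_depth = as.integer(max_depth)),
            class = "seg_params")
}

gaussian_kernel <- function(k, sigma) {
  if (sigma <= 0) sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  i <- seq.int(-(k - 1L) / 2L, (k - 1L) / 2L)
  g <- exp(-i^2 / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)

# H x W x 3 integer RGB (0-255) -> list of L, a, b matrices (L in [0, 100])
rgb_to_lab <- function(pixels) {
  d <- dim(pixels)
  m <- matrix(as.double(pixels), ncol = 3L) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

conv2 <- function(x, kernel) {
  as.matrix(EBImage::filter2(x, kernel, boundary = "replicate"))
}

# gradient magnitude of the blurred L channel on a fixed 0-255 scale:
# L is normalised to [0, 1]; each Sobel response is bounded by 4 (the kernel
# weight sum), so magnitude * 255 / 4 puts a full black-white step at ~255.
gradient_magnitude <- function(pixels, params) {
  lab <- rgb_to_lab(pixels)
  kern <- gaussian_kernel(params$blur_kernel, params$blur_sigma)
  Lb <- conv2(lab$L / 100, kern)
  gx <- conv2(Lb, sobel_x)
  gy <- conv2(Lb, t(sobel_x))
  pmin(sqrt(gx^2 + gy^2) * (255 / 4), 255)
}

#' Compute the binary edge map of an image
#'
#' Converts the image to CIELAB, applies Gaussian blur to remove noise,
#' takes Sobel gradients in x and y on the lightness channel, combines them
#' into a gradient magnitude rescaled to 0--255, and thresholds. "On" pixels
#' mark edges in the source image.
#'
#' @param image A [source_image], at least as large as the blur kernel.
#' @param params A [seg_params] object.
#' @return An `edge_map`: list with a logical `mask` (same height/width as the
#'   image) and the underlying `magnitude` matrix.
#' @export
compute_edge_map <- function(image, params = seg_params()) {
  h <- img_height(image); w <- img_width(image)
  if (h < 3L || w < 3L) stop_param("image must be at least 3 x 3 pixels")
  if (h < params$blur_kernel || w < params$blur_kernel)
    stop_param("image is smaller than the blur kernel")
  mag <- gradient_magnitude(image$pixels, params)
  structure(list(mask = mag >= params$edge_threshold, magnitude = mag,
                 width = w, height = h),
            class = "edge_map")
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find pass.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  lab[lab > 0L] <- relabel[lab[lab > 0L]]
  lab
}

# bounding rects (0-based half-open, pixel units) of labelled components
component_rects <- function(lab) {
  idx <- which(lab > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(tibble(x0 = integer(), y0 = integer(), x1 = integer(), y1 = integer()))
  l <- lab[idx]
  tibble(
    x0 = as.integer(tapply(idx[, 2], l, min) - 1L),
    y0 = as.integer(tapply(idx[, 1], l, min) - 1L),
    x1 = as.integer(tapply(idx[, 2], l, max)),
    y1 = as.integer(tapply(idx[, 1], l, max))
  )
}

# reading order: group into rows top-to-bottom (a box joins the current row
# when its top lies within half the row-opening box's height), then
# left-to-right within each row
reading_order <- function(rects) {
  n <- nrow(rects)
  if (n <= 1L) return(seq_len(n))
  ord <- order(rects$y0, rects$x0)
  row_id <- integer(n)
  cur <- 0L; row_y0 <- 0; row_h <- 0
  for (i in ord) {
    if (cur == 0L || rects$y0[i] >= row_y0 + 0.5 * row_h) {
      cur <- cur + 1L
      row_y0 <- rects$y0[i]
      row_h <- rects$y1[i] - rects$y0[i]
    }
    row_id[i] <- cur
  }
  order(row_id, rects$x0, rects$y0)
}

#' Extract bounding rectangles from an edge map
#'
#' Traces connected edge components and computes each component's bounding
#' rectangle. Rectangles are processed recursively to find edges-within-edges
#' (specimens inside unit trays): a rectangle whose area exceeds
#' `max_box_fraction` of the image is treated as a container, its interior is
#' re-processed one level deeper, and it is replaced by its children when any
#' are found. Rectangles below `min_box_fraction` are discarded. Output is in
#' reading order (rows top-to-bottom, then left-to-right).
#'
#' @details With connected-component tracing, the components enclosed by a
#'   container are already present in the component list, so "re-processing a
#'   container's interior" amounts to identifying the components whose
#'   rectangles it encloses: the container's rectangle is dropped in favour of
#'   the enclosed ones, applied once per remaining recursion level so nested
#'   containers unwrap one level at a time.
#'
#' @param edge_map An `edge_map` from [compute_edge_map()].
#' @param params A [seg_params] object.
#' @param depth Recursion levels (default `params$max_depth`); at `depth = 1`
#'   the result is exactly the area-filtered connected-component rectangles.
#' @return Tibble of pixel rectangles (`x0, y0, x1, y1`, 0-based half-open).
#' @export
extract_boxes <- function(edge_map, params = seg_params(), depth = params$max_depth) {
  if (!is_count(depth)) stop_param("`depth` must be >= 1")
  img_area <- edge_map$width * edge_map$height
  lab <- label_components(edge_map$mask)
  rects <- component_rects(lab)
  frac <- (rects$x1 - rects$x0) * (rects$y1 - rects$y0) / img_area
  rects <- rects[frac >= params$min_box_fraction, ]
  for (lev in seq_len(depth - 1L)) {
    frac <- (rects$x1 - rects$x0) * (rects$y1 - rects$y0) / img_area
    drop <- logical(nrow(rects))
    for (i in which(frac > params$max_box_fraction)) {
      children <- rects$x0 >= rects$x0[i] & rects$x1 <= rects$x1[i] &
        rects$y0 >= rects$y0[i] & rects$y1 <= rects$y1[i] &
        seq_len(nrow(rects)) != i & frac < frac[i]
      if (any(children & !drop)) drop[i] <- TRUE
    }
    if (!any(drop)) break
    rects <- rects[!drop, ]
  }
  rects[reading_order(rects), ]
}

#' Segment a scan into specimen bounding boxes
#'
#' Runs the automatic pipeline — edge map then recursive contour extraction —
#' and returns normalized boxes. The algorithm operates on the document
#' thumbnail; boxes are normalized by the thumbnail dimensions so they remain
#' valid at full resolution. Deterministic: identical pixels and parameters
#' give identical output.
#'
#' @param image A [source_image] (normally the thumbnail).
#' @param params A [seg_params] object.
#' @return A boxes tibble (rotation 0, empty metadata), in reading order.
#' @export
segment_image <- function(image, params = seg_params()) {
  em <- compute_edge_map(image, params)
  rects <- extract_boxes(em, params)
  if (nrow(rects) == 0L) return(boxes())
  norm <- normalize_rect(rects$x0, rects$y0, rects$x1, rects$y1,
                         em$width, em$height)
  as_boxes(norm)
}

#' Segmentation algorithm registry
#'
#' Any callable `function(image, params) -> boxes` can replace the default
#' edge-based segmenter, mirroring a plugin design: code modules that examine
#' and modify the list of bounding boxes.
#'
#' @param name Registry key.
#' @param fn A `function(image, params)` returning a boxes tibble.
#' @return `register_segmenter()` returns `fn` invisibly; `get_segmenter()`
#'   the registered function.
#' @export
register_segmenter <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  the$segmenters[[name]] <- fn
  invisible(fn)
}

#' @rdname register_segmenter
#' @export
get_segmenter <- function(name = "edge") {
  fn <- the$segmenters[[name]]
  if (is.null(fn)) stop_param(sprintf("no segmenter registered under '%s'", name))
  fn
}
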