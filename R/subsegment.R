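#' Split one box into per-specimen boxes with a marker-seeded watershed
#'
#' When automatic segmentation could not discriminate between touching
#' specimens, the user marks each individual specimen inside the box. The
#' gradient magnitude of the blurred lightness channel is treated as a
#' topographic surface and flooded from the markers: regions grow outwards by
#' ascending gradient level until every pixel of the parent rectangle belongs
#' to a marker's catchment. Each catchment's bounding rectangle, clipped to
#' the parent, becomes one box — exactly one per marker, each containing its
#' marker.
#'
#' @param image A [source_image] (normally the thumbnail).
#' @param parent A single box: one-row boxes tibble (or a list with
#'   `x0, y0, x1, y1` normalized coordinates).
#' @param markers A two-column matrix or data frame of marker pixel
#'   coordinates `(x, y)` (1-based column/row in `image`), one row per
#'   specimen; every marker must lie inside the parent's pixel rectangle.
#' @param params A [seg_params] object (blur settings are reused for the
#'   gradient surface).
#' @return A boxes tibble with one row per marker, in marker order.
#' @export
subsegment <- function(image, parent, markers, params = seg_params()) {
  if (is.data.frame(parent)) {
    if (nrow(parent) != 1L) stop_param("`parent` must be a single box")
    parent <- as.list(parent[1, ])
  }
  w <- img_width(image); h <- img_height(image)
  rect <- denormalize_rect(parent, w, h)
  markers <- as.matrix(as.data.frame(markers)[, 1:2])
  storage.mode(markers) <- "integer"
  if (nrow(markers) < 1L) stop_param("at least one marker is required")
  inside <- markers[, 1] > rect["x0"] & markers[, 1] <= rect["x1"] &
    markers[, 2] > rect["y0"] & markers[, 2] <= rect["y1"]
  if (any(!inside))
    stop_param(sprintf("marker %d lies outside the parent box", which(!inside)[1]))
  if (anyDuplicated(markers)) stop_param("markers must be distinct pixels")
  rows <- (rect["y0"] + 1L):rect["y1"]
  cols <- (rect["x0"] + 1L):rect["x1"]
  if (length(rows) < params$blur_kernel || length(cols) < params$blur_kernel)
    stop_param("parent box is smaller than the blur kernel")
  sub <- image$pixels[rows, cols, , drop = FALSE]
  surface <- floor(gradient_magnitude(sub, params))
  seeds <- cbind(row = markers[, 2] - rect["y0"], col = markers[, 1] - rect["x0"])
  lab <- flood_from_markers(surface, seeds)
  out <- vector("list", nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    pix <- which(lab == k, arr.ind = TRUE)
    out[[k]] <- normalize_rect(
      x0 = rect["x0"] + min(pix[, 2]) - 1L, y0 = rect["y0"] + min(pix[, 1]) - 1L,
      x1 = rect["x0"] + max(pix[, 2]),      y1 = rect["y0"] + max(pix[, 1]),
      width = w, height = h)
  }
  as_boxes(bind_rows(out))
}

# flood catchment basins: iterative marker-region growing by ascending
# gradient level; 4-connected, deterministic (fixed neighbour precedence
# up, left, down, right resolves contested pixels)
flood_from_markers <- function(surface, seeds) {
  nr <- nrow(surface); nc <- ncol(surface)
  lab <- matrix(0L, nr, nc)
  lab[cbind(seeds[, "row"], seeds[, "col"])] <- seq_len(nrow(seeds))
  shift_up    <- function(m) rbind(m[-1, , drop = FALSE], rep(0L, nc))   # neighbour below
  shift_down  <- function(m) rbind(rep(0L, nc), m[-nr, , drop = FALSE])  # neighbour above
  shift_left  <- function(m) cbind(m[, -1, drop = FALSE], rep(0L, nr))   # neighbour right
  shift_right <- function(m) cbind(rep(0L, nr), m[, -nc, drop = FALSE])  # neighbour left
  for (lev in sort(unique(as.vector(surface)))) {
    active <- surface <= lev
    repeat {
      nb_up <- shift_down(lab); nb_left <- shift_right(lab)
      nb_down <- shift_up(lab); nb_right <- shift_left(lab)
      cand <- nb_up
      cand[cand == 0L] <- nb_left[cand == 0L]
      cand[cand == 0L] <- nb_down[cand == 0L]
      cand[cand == 0L] <- nb_right[cand == 0L]
      grow <- lab == 0L & active & cand > 0L
      if (!any(grow)) break
      lab[grow] <- cand[grow]
    }
    if (!any(lab == 0L)) break
  }
  lab
}
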