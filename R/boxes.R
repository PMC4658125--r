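#' Bounding-box tables
#'
#' Boxes are kept as a tibble with one row per specimen: normalized
#' coordinates `x0, y0, x1, y1` in `[0, 1]` relative to the scan (half-open in
#' pixel space after denormalization), a clockwise `rotation` restricted to
#' 0/90/180/270 degrees, and a `fields` list-column holding each box's
#' metadata as a named character vector. Coordinates are stored rounded to 6
#' decimal places, the precision used by document sidecars.
#'
#' @param x0,y0,x1,y1 Numeric vectors of normalized coordinates.
#' @param rotation Integer vector of rotations (degrees clockwise).
#' @param fields List of named character vectors (one per box).
#' @return A boxes tibble.
#' @export
boxes <- function(x0 = double(), y0 = double(), x1 = double(), y1 = double(),
                  rotation = integer(length(x0)),
                  fields = rep(list(stats::setNames(character(), character())), length(x0))) {
  as_boxes(tibble(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                  rotation = rotation, fields = fields))
}

#' @rdname boxes
#' @param x A data frame with columns `x0, y0, x1, y1` and optionally
#'   `rotation` and `fields`.
#' @export
as_boxes <- function(x) {
  x <- as_tibble(x)
  need <- c("x0", "y0", "x1", "y1")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_param(paste0("missing box columns: ", paste(miss, collapse = ", ")))
  if (!"rotation" %in% names(x)) x$rotation <- integer(nrow(x))
  if (!"fields" %in% names(x))
    x$fields <- rep(list(stats::setNames(character(), character())), nrow(x))
  x <- x[, c("x0", "y0", "x1", "y1", "rotation", "fields")]
  for (v in need) x[[v]] <- round_coord(as.double(x[[v]]))
  x$rotation <- as.integer(x$rotation)
  x$fields <- map(x$fields, function(f) {
    f <- as.character(f) |> stats::setNames(names(f) %||% character())
    if (length(f) && (is.null(names(f)) || any(!nzchar(names(f)))))
      stop_param("box metadata values must be named")
    f
  })
  validate_boxes(x)
  x
}

validate_boxes <- function(x) {
  ok_range <- x$x0 >= 0 & x$x0 < x$x1 & x$x1 <= 1 &
    x$y0 >= 0 & x$y0 < x$y1 & x$y1 <= 1
  if (any(!ok_range))
    stop_param(sprintf("invalid box rect in row %d: need 0 <= x0 < x1 <= 1 and 0 <= y0 < y1 <= 1",
                       which(!ok_range)[1]))
  bad_rot <- !x$rotation %in% c(0L, 90L, 180L, 270L)
  if (any(bad_rot))
    stop_param(sprintf("rotation must be one of 0, 90, 180, 270 (row %d)", which(bad_rot)[1]))
  invisible(x)
}

# normalized box -> 0-based half-open pixel rect against (width, height)
denormalize_rect <- function(box, width, height) {
  r <- c(x0 = round(box$x0 * width), y0 = round(box$y0 * height),
         x1 = round(box$x1 * width), y1 = round(box$y1 * height))
  storage.mode(r) <- "integer"
  r
}

# 0-based half-open pixel rect -> normalized coordinates
normalize_rect <- function(x0, y0, x1, y1, width, height) {
  tibble(x0 = round_coord(x0 / width), y0 = round_coord(y0 / height),
         x1 = round_coord(x1 / width), y1 = round_coord(y1 / height))
}

boxes_equal <- function(a, b) {
  isTRUE(all.equal(a[c("x0", "y0", "x1", "y1")], b[c("x0", "y0", "x1", "y1")],
                   tolerance = 1e-9)) &&
    identical(a$rotation, b$rotation) &&
    length(a$fields) == length(b$fields) &&
    all(map_lgl(seq_along(a$fields), function(i) {
      fa <- a$fields[[i]]; fb <- b$fields[[i]]
      length(fa) == length(fb) && setequal(names(fa), names(fb)) &&
        all(fa[names(fb)] == fb)
    }))
}

# intersection-over-union between two sets of normalized rects (matrix result)
iou_matrix <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(0, nrow(a), nrow(b)))
  ix0 <- outer(a$x0, b$x0, pmax); iy0 <- outer(a$y0, b$y0, pmax)
  ix1 <- outer(a$x1, b$x1, pmin); iy1 <- outer(a$y1, b$y1, pmin)
  inter <- pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0)
  area_a <- (a$x1 - a$x0) * (a$y1 - a$y0)
  area_b <- (b$x1 - b$x0) * (b$y1 - b$y0)
  inter / (outer(area_a, area_b, `+`) - inter)
}
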