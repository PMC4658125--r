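#' Documents: the unit of persistence
#'
#' A document ties together a full-resolution scan, its working thumbnail and
#' the ordered list of specimen boxes (with metadata). It is persisted as a
#' JSON sidecar `<scan-stem>.inselect` next to the scan: human-inspectable,
#' diff-able and order-preserving. Normalized coordinates are stored with 6
#' decimal places.
#'
#' @param scan_path Path to the full-resolution scan.
#' @param thumbnail_path Path to the JPEG thumbnail.
#' @param thumbnail_width Width of the thumbnail in pixels.
#' @param boxes A boxes tibble (see [boxes()]); empty for a fresh document.
#' @param template_name Optional name of the metadata template in use.
#' @return An `inselect_doc` object.
#' @export
new_document <- function(scan_path, thumbnail_path, thumbnail_width = 4096L,
                         boxes = drawerseg::boxes(), template_name = NA_character_) {
  if (!is_count(thumbnail_width)) stop_param("`thumbnail_width` must be a positive integer")
  structure(
    list(scan_path = as.character(scan_path),
         thumbnail_path = as.character(thumbnail_path),
         thumbnail_width = as.integer(thumbnail_width),
         template_name = as.character(template_name),
         boxes = as_boxes(boxes)),
    class = "inselect_doc"
  )
}

#' @export
print.inselect_doc <- function(x, ...) {
  cat(sprintf("<inselect_doc> scan: %s\n  thumbnail: %s (width %d)\n  boxes: %d%s\n",
              x$scan_path, x$thumbnail_path, x$thumbnail_width, nrow(x$boxes),
              if (is.na(x$template_name)) "" else paste0("\n  template: ", x$template_name)))
  invisible(x)
}

document_path <- function(scan_path) {
  file.path(dirname(scan_path),
            paste0(tools::file_path_sans_ext(basename(scan_path)), ".inselect"))
}

thumbnail_path_for <- function(scan_path) {
  file.path(dirname(scan_path),
            paste0(tools::file_path_sans_ext(basename(scan_path)), "_thumbnail.jpg"))
}

#' Persist a document to its JSON sidecar
#'
#' @param doc An `inselect_doc`.
#' @param path Output path; defaults to `<scan-stem>.inselect` next to the scan.
#' @return The path written, invisibly.
#' @export
save_document <- function(doc, path = document_path(doc$scan_path)) {
  stopifnot(inherits(doc, "inselect_doc"))
  validate_boxes(doc$boxes)
  payload <- list(
    format = "drawerseg-document",
    version = 1L,
    scan = doc$scan_path,
    thumbnail = list(path = doc$thumbnail_path, width = doc$thumbnail_width),
    template = if (is.na(doc$template_name)) NULL else doc$template_name,
    boxes = pmap(doc$boxes, function(x0, y0, x1, y1, rotation, fields) {
      list(rect = round_coord(c(x0, y0, x1, y1)), rotation = rotation,
           fields = as.list(fields))
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

need_key <- function(x, key, where) {
  if (is.null(x[[key]])) stop_corrupt(sprintf("document sidecar missing key '%s' in %s", key, where))
  x[[key]]
}

#' Load a document from a JSON sidecar
#'
#' `load_document(save_document(doc))` is the identity, including box order,
#' rotations and metadata values. Schema violations raise a document-corrupt
#' error naming the offending key.
#'
#' @param path Path to a `.inselect` sidecar.
#' @return An `inselect_doc`.
#' @export
load_document <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("document not found: %s", path))
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop_corrupt(sprintf("not valid JSON: %s", path)))
  scan <- need_key(raw, "scan", path)
  thumb <- need_key(raw, "thumbnail", path)
  tpath <- need_key(thumb, "path", "thumbnail")
  twidth <- need_key(thumb, "width", "thumbnail")
  if (!is.numeric(twidth) || twidth < 1) stop_corrupt("invalid value for key 'thumbnail.width'")
  if (is.null(raw$boxes)) stop_corrupt(sprintf("document sidecar missing key 'boxes' in %s", path))
  bx <- map(raw$boxes, function(b) {
    rect <- need_key(b, "rect", "box")
    if (length(rect) != 4L || !all(map_lgl(rect, is.numeric)))
      stop_corrupt("invalid value for key 'rect': expected 4 numbers")
    rect <- as.double(unlist(rect))
    if (!(rect[1] >= 0 && rect[1] < rect[3] && rect[3] <= 1 &&
          rect[2] >= 0 && rect[2] < rect[4] && rect[4] <= 1))
      stop_corrupt("invalid value for key 'rect': need 0 <= x0 < x1 <= 1, 0 <= y0 < y1 <= 1")
    rot <- b$rotation %||% 0L
    if (!rot %in% c(0, 90, 180, 270))
      stop_corrupt("invalid value for key 'rotation': must be 0, 90, 180 or 270")
    f <- b$fields %||% list()
    tibble(x0 = rect[1], y0 = rect[2], x1 = rect[3], y1 = rect[4],
           rotation = as.integer(rot),
           fields = list(stats::setNames(as.character(unlist(f) %||% character()),
                                         names(f) %||% character())))
  })
  new_document(
    scan_path = scan,
    thumbnail_path = tpath,
    thumbnail_width = as.integer(twidth),
    template_name = if (is.null(raw$template)) NA_character_ else raw$template,
    boxes = if (length(bx)) as_boxes(bind_rows(bx)) else drawerseg::boxes()
  )
}

#' Ingest a scan: create an empty document plus thumbnail
#'
#' The first stage of the batch workflow: reads the scanned image, writes a
#' JPEG thumbnail (at the template's width if given, else 4,096 px) and saves
#' an empty document sidecar next to the scan. An existing document is left
#' untouched unless `overwrite = TRUE`; the returned document then carries
#' `attr(, "skipped") = TRUE`.
#'
#' @param scan_path Path to the scan image.
#' @param template Optional `template_spec` supplying the thumbnail width.
#' @param width Explicit thumbnail width; overrides the template's.
#' @param overwrite Replace an existing document? Default `FALSE` (skip).
#' @return The `inselect_doc`, invisibly carrying a `skipped` attribute.
#' @export
ingest <- function(scan_path, template = NULL, width = NULL, overwrite = FALSE) {
  doc_path <- document_path(scan_path)
  if (file.exists(doc_path) && !overwrite) {
    doc <- load_document(doc_path)
    attr(doc, "skipped") <- TRUE
    return(invisible(doc))
  }
  image <- load_image(scan_path)
  width <- width %||% (if (!is.null(template)) template$thumbnail_width else 4096L)
  thumb <- make_thumbnail(image, width)
  tpath <- thumbnail_path_for(scan_path)
  write_image(thumb, tpath, quality = 85L) # fixed quality keeps sizes reproducible
  doc <- new_document(scan_path = scan_path, thumbnail_path = tpath,
                      thumbnail_width = as.integer(width),
                      template_name = if (is.null(template)) NA_character_ else template$name)
  save_document(doc, doc_path)
  attr(doc, "skipped") <- FALSE
  invisible(doc)
}

#' Replace a document's boxes
#'
#' Automatic segmentation replaces any existing boxes. Existing boxes that
#' carry metadata are protected: replacing them requires `force = TRUE`,
#' otherwise a refusal error is raised so batch runs cannot silently destroy
#' curated metadata.
#'
#' @param doc An `inselect_doc`.
#' @param new_boxes A boxes tibble.
#' @param force Discard existing metadata-bearing boxes without complaint?
#' @return The updated document.
#' @export
replace_boxes <- function(doc, new_boxes, force = FALSE) {
  stopifnot(inherits(doc, "inselect_doc"))
  has_meta <- any(map_lgl(doc$boxes$fields, function(f) length(f) > 0))
  if (has_meta && !force)
    stop_refusal("existing boxes carry metadata; use `force = TRUE` to discard them")
  doc$boxes <- as_boxes(new_boxes)
  doc
}
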