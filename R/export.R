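#' Crop one box out of the full-resolution scan
#'
#' The box is denormalized against the full-resolution dimensions (not the
#' thumbnail), the pixels are copied, and the box's rotation is applied
#' clockwise; 90/270 degree rotations swap the output dimensions. Boxes
#' extending past the image edge are clamped to the boundary — no pixels are
#' invented.
#'
#' @param source A [source_image] at full resolution.
#' @param box A one-row boxes tibble (or list with `x0, y0, x1, y1`,
#'   `rotation`).
#' @return A [source_image] holding the rotated crop.
#' @export
crop_box <- function(source, box) {
  if (is.data.frame(box)) {
    if (nrow(box) != 1L) stop_param("`box` must be a single box")
    box <- as.list(box[1, ])
  }
  w <- img_width(source); h <- img_height(source)
  r <- denormalize_rect(box, w, h)
  r["x0"] <- max(r["x0"], 0L); r["y0"] <- max(r["y0"], 0L)
  r["x1"] <- min(r["x1"], w); r["y1"] <- min(r["y1"], h)
  if (r["x1"] - r["x0"] < 1L || r["y1"] - r["y0"] < 1L)
    stop_geometry("box denormalizes to an empty pixel rectangle")
  px <- source$pixels[(r["y0"] + 1L):r["y1"], (r["x0"] + 1L):r["x1"], , drop = FALSE]
  source_image(rotate_cw(px, box$rotation %||% 0L), path = source$path)
}

# clockwise rotation of an H x W x C array by multiples of 90 degrees
rotate_cw <- function(px, rotation) {
  rotation <- as.integer(rotation) %% 360L
  if (rotation == 0L) return(px)
  h <- dim(px)[1]; w <- dim(px)[2]
  t_ <- aperm(px, c(2L, 1L, 3L))
  switch(as.character(rotation),
         "90"  = t_[, h:1, , drop = FALSE],
         "180" = px[h:1, w:1, , drop = FALSE],
         "270" = t_[w:1, , , drop = FALSE],
         stop_param("rotation must be a multiple of 90"))
}

#' Build a crop's file name from its metadata
#'
#' Joins the values of the template's `crop_filename` fields with `_` (so a
#' catalog number becomes the file name). When the template defines no
#' pattern or any pattern field is empty, falls back to the box's zero-padded
#' 1-based index (width 4). Path separators, whitespace and control
#' characters are sanitized to `-`.
#'
#' @param box A one-row boxes tibble or list with a `fields` entry.
#' @param index 1-based position of the box in the document.
#' @param template Optional `template_spec`.
#' @param ext File extension including the dot (default `.jpg`).
#' @return A filesystem-safe file name.
#' @export
crop_filename <- function(box, index, template = NULL, ext = ".jpg") {
  fields <- if (is.data.frame(box)) box$fields[[1]] else box$fields
  pattern <- if (!is.null(template)) template$crop_filename else character()
  stem <- NULL
  if (length(pattern)) {
    vals <- map_chr(pattern, function(nm) {
      if (nm %in% names(fields)) fields[[nm]] else NA_character_
    })
    if (!anyNA(vals) && all(nzchar(vals))) stem <- paste(vals, collapse = "_")
  }
  if (is.null(stem)) stem <- sprintf("%04d", as.integer(index))
  stem <- gsub("[/\\\\[:space:][:cntrl:]]+", "-", stem)
  paste0(stem, ext)
}

#' Write per-specimen crops for a document
#'
#' Writes one image per box, in document box order, cropped from the
#' full-resolution scan (loaded once per document). File name collisions are
#' resolved by appending `-1`, `-2`, ... before the extension.
#'
#' @param doc An `inselect_doc` whose scan is readable.
#' @param template Optional `template_spec` driving file names.
#' @param out_dir Output directory (created if needed).
#' @param format `"jpg"` (quality 95) or `"tiff"`.
#' @return A tibble with one row per crop: `box` (index) and `path`.
#' @export
export_crops <- function(doc, template = NULL, out_dir = ".",
                         format = c("jpg", "tiff")) {
  format <- match.arg(format)
  ext <- paste0(".", format)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    abort(sprintf("cannot create output directory %s", out_dir), class = "drawerseg_io_error")
  if (!file.exists(doc$scan_path))
    stop_input(sprintf("scan not found: %s", doc$scan_path))
  n <- nrow(doc$boxes)
  if (n == 0L) return(tibble(box = integer(), path = character()))
  full <- load_image(doc$scan_path)
  used <- character()
  paths <- character(n)
  for (i in seq_len(n)) {
    name <- crop_filename(doc$boxes[i, ], i, template, ext = ext)
    stem <- tools::file_path_sans_ext(name)
    k <- 0L
    while (name %in% used) {
      k <- k + 1L
      name <- paste0(stem, "-", k, ext)
    }
    used <- c(used, name)
    crop <- crop_box(full, doc$boxes[i, ])
    paths[i] <- file.path(out_dir, name)
    write_image(crop, paths[i], quality = 95L)
  }
  tibble(box = seq_len(n), path = paths)
}

#' Export a document's metadata as a CSV table
#'
#' One row per box in document order. Fixed leading columns — scan file stem,
#' 1-based box index, normalized coordinates (6 decimals) and rotation — are
#' followed by one column per template field (template order), or by the
#' union of observed field names when no template is given. Optionally a
#' `valid` column records per-box template validation. Written files are
#' RFC-4180 quoted UTF-8.
#'
#' @param doc An `inselect_doc`.
#' @param template Optional `template_spec`.
#' @param path Optional output path; when given the CSV is written there.
#' @param include_valid Add a logical `valid` column (requires a template)?
#' @return The export tibble, invisibly when `path` is given.
#' @export
export_csv <- function(doc, template = NULL, path = NULL, include_valid = FALSE) {
  n <- nrow(doc$boxes)
  field_names <- if (!is.null(template)) template$fields$name
    else unique(unlist(map(doc$boxes$fields, names))) %||% character()
  base_tbl <- tibble(
    file = tools::file_path_sans_ext(basename(doc$scan_path)),
    box = seq_len(n),
    x0 = round_coord(doc$boxes$x0), y0 = round_coord(doc$boxes$y0),
    x1 = round_coord(doc$boxes$x1), y1 = round_coord(doc$boxes$y1),
    rotation = doc$boxes$rotation
  )
  if (n == 0L) base_tbl <- base_tbl[0, ]
  for (nm in field_names)
    base_tbl[[nm]] <- map_chr(doc$boxes$fields, function(f) {
      if (nm %in% names(f)) f[[nm]] else ""
    }) %||% character()
  if (include_valid) {
    if (is.null(template)) stop_param("`include_valid` requires a template")
    base_tbl$valid <- map_lgl(doc$boxes$fields, function(f) validate_box(f, template)$ok)
  }
  if (!is.null(path)) {
    readr::write_csv(base_tbl, path, na = "")
    return(invisible(base_tbl))
  }
  base_tbl
}

csv_path_for <- function(scan_path) {
  file.path(dirname(scan_path),
            paste0(tools::file_path_sans_ext(basename(scan_path)), ".csv"))
}
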